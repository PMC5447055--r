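#' Pipeline configuration
#'
#' Collects every knob of the 13-step workflow. Steps 1, 3 and 6 of the
#' classical workflow (template-to-native registration, probabilistic
#' tractography, inverse warping) are external stages: the pipeline
#' ingests streamline-count profiles already expressed in one common voxel
#' grid and logs those steps as external.
#'
#' @param data_dir Directory with the ingested cohort (see
#'   [write_cohort()] for the layout).
#' @param working_dir Output workspace root.
#' @param roi ROI name (file-name stem of the mask/profiles).
#' @param k_min,k_max Cluster-count range (defaults 2 and 12).
#' @param threshold_p Connection-probability cutoff (default 0.0004).
#' @param n_samples Streamlines per seed voxel (default 5000).
#' @param block_mm Down-sampling block size in mm (default 5).
#' @param group_threshold Coincidence-matrix threshold (default 0.5).
#' @param n_reps Split-half repetitions (default 100).
#' @param connectivity Neighborhood for the continuity vote (default 26).
#' @param master_seed Master seed for all randomness.
#' @param steps Steps to run, subset of 0..12.
#' @param n_workers Parallel workers for independent units.
#' @param n_restarts k-means restarts (default 100).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, working_dir, roi = "roi",
                            k_min = 2, k_max = 12, threshold_p = 0.0004,
                            n_samples = 5000, block_mm = 5,
                            group_threshold = 0.5, n_reps = 100,
                            connectivity = 26, master_seed = 1L,
                            steps = 0:12, n_workers = 1, n_restarts = 100) {
  stopifnot(k_min >= 2, k_min <= k_max, all(steps %in% 0:12))
  structure(
    list(
      data_dir = data_dir, working_dir = working_dir, roi = roi,
      k_min = as.integer(k_min), k_max = as.integer(k_max),
      threshold_p = threshold_p, n_samples = as.integer(n_samples),
      block_mm = block_mm, group_threshold = group_threshold,
      n_reps = as.integer(n_reps), connectivity = as.integer(connectivity),
      master_seed = as.integer(master_seed), steps = as.integer(steps),
      n_workers = as.integer(n_workers), n_restarts = as.integer(n_restarts)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (e.g.
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param ... Named overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

roi_dir <- function(config) file.path(config$working_dir, config$roi)

subject_ids <- function(config) {
  meta <- yaml::read_yaml(
    file.path(config$data_dir, paste0(config$roi, "_meta.yaml"))
  )
  unlist(meta$subjects)
}

cohort_meta <- function(config) {
  yaml::read_yaml(file.path(config$data_dir, paste0(config$roi, "_meta.yaml")))
}

pipeline_paths <- function(config) {
  rd <- roi_dir(config)
  subs <- subject_ids(config)
  ks <- config$k_min:config$k_max
  list(
    roi_dir = rd,
    log_dir = file.path(rd, "log"),
    group_dir = file.path(rd, "group"),
    subject_dirs = stats::setNames(file.path(rd, subs), subs),
    coords = file.path(rd, paste0(config$roi, "_coords.txt")),
    native = stats::setNames(
      file.path(rd, subs, paste0(config$roi, "_native_matrix.txt")), subs
    ),
    cc = stats::setNames(
      file.path(rd, subs, paste0(config$roi, "_cross_correlation.txt")), subs
    ),
    parc = function(sub, k) {
      file.path(rd, sub, sprintf("%s_k%d_parcellation.nii.gz", config$roi, k))
    },
    relabeled = function(sub, k) {
      file.path(rd, sub, sprintf("%s_k%d_relabeled.nii.gz", config$roi, k))
    },
    scheme = function(k) {
      file.path(
        rd, "group",
        sprintf("%s_k%d_group_scheme.nii.gz", config$roi, k)
      )
    },
    mpm = function(k) {
      file.path(rd, "group", sprintf("%s_k%d_mpm.nii.gz", config$roi, k))
    },
    mpm_denoised = function(k) {
      file.path(
        rd, "group",
        sprintf("%s_k%d_mpm_denoised.nii.gz", config$roi, k)
      )
    },
    validity = file.path(rd, "group", paste0(config$roi, "_validity.tsv")),
    replicates = file.path(rd, "group", paste0(config$roi, "_replicates.tsv")),
    suggestion = file.path(rd, "group", paste0(config$roi, "_suggested_k.txt")),
    plot = file.path(rd, "group", paste0(config$roi, "_validity_plot.pdf")),
    subjects = subs, ks = ks
  )
}

#' Initialize the workspace directory tree
#'
#' Creates `<working_dir>/<roi>/` with `log/`, `group/` and one
#' subdirectory per subject. Idempotent: rerunning changes nothing.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the ROI directory path.
#' @export
init_workspace <- function(config) {
  if (!dir.exists(config$data_dir)) {
    stop("data_dir does not exist: ", config$data_dir, call. = FALSE)
  }
  p <- pipeline_paths(config)
  for (d in c(p$roi_dir, p$log_dir, p$group_dir, p$subject_dirs)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  invisible(p$roi_dir)
}

valid_matrix_file <- function(path) {
  file.exists(path) &&
    !inherits(try(read_matrix(path), silent = TRUE), "try-error")
}

step_outputs_ok <- function(step, config, p) {
  switch(as.character(step),
    "0" = all(dir.exists(c(p$log_dir, p$group_dir, p$subject_dirs))),
    "1" = TRUE,
    "2" = file.exists(p$coords),
    "3" = TRUE,
    "4" = all(vapply(c(p$native, p$cc), valid_matrix_file, logical(1))),
    "5" = all(vapply(
      p$subjects,
      function(s) all(file.exists(vapply(p$ks, function(k) p$parc(s, k), character(1)))),
      logical(1)
    )),
    "6" = TRUE,
    "7" = all(file.exists(vapply(p$ks, p$scheme, character(1)))),
    "8" = all(vapply(
      p$subjects,
      function(s) {
        all(file.exists(vapply(p$ks, function(k) p$relabeled(s, k), character(1))))
      },
      logical(1)
    )),
    "9" = all(file.exists(vapply(p$ks, p$mpm, character(1)))),
    "10" = all(file.exists(vapply(p$ks, p$mpm_denoised, character(1)))),
    "11" = file.exists(p$validity),
    "12" = file.exists(p$suggestion),
    FALSE
  )
}

# Earliest prerequisite step whose outputs are missing, or NULL.
unmet_dependency <- function(step, config, p) {
  deps <- switch(as.character(step),
    "2" = 0, "4" = c(0, 2), "5" = c(0, 4), "7" = c(0, 5), "8" = c(0, 5, 7),
    "9" = c(0, 8), "10" = c(0, 9), "11" = c(0, 4, 5, 8, 10),
    "12" = c(0, 11), integer(0)
  )
  for (d in deps) {
    if (!step_outputs_ok(d, config, p)) {
      return(d)
    }
  }
  NULL
}

run_step <- function(step, config, p) {
  meta <- cohort_meta(config)
  voxel_size <- as.numeric(unlist(meta$voxel_size))
  target_shape <- as.integer(unlist(meta$target_shape))
  affine <- diag(c(voxel_size, 1))
  mask <- read_label_volume(
    file.path(config$data_dir, paste0(config$roi, "_mask.nii.gz"))
  )
  shape <- dim(mask$data)
  coords_of <- function() read_seed_coordinates(p$coords)

  switch(as.character(step),
    "0" = init_workspace(config),
    "2" = {
      write_seed_coordinates(extract_seed_coordinates(mask), p$coords)
    },
    "4" = {
      coords <- coords_of()
      invisible(run_units(p$subjects, function(s) {
        profiles <- read_matrix(
          file.path(config$data_dir, s, paste0(config$roi, "_profile.txt"))
        )
        native <- build_native_matrix(
          profiles, coords, target_shape, voxel_size,
          threshold_p = config$threshold_p, n_samples = config$n_samples,
          block_mm = config$block_mm
        )
        write_matrix(native, p$native[[s]])
        write_matrix(cross_correlation(native), p$cc[[s]])
        NULL
      }, config$n_workers))
    },
    "5" = {
      coords <- coords_of()
      invisible(run_units(seq_along(p$subjects), function(si) {
        s <- p$subjects[si]
        cc <- read_matrix(p$cc[[s]])
        sols <- cluster_solutions(
          cc, coords, shape,
          k_min = config$k_min, k_max = config$k_max,
          seed = derive_seed(config$master_seed, si),
          n_restarts = config$n_restarts
        )
        for (k in p$ks) {
          write_label_volume(
            parcellation_volume(sols[[paste0("k", k)]], affine),
            p$parc(s, k)
          )
        }
        NULL
      }, config$n_workers))
    },
    "7" = {
      for (k in p$ks) {
        parcs <- lapply(p$subjects, function(s) {
          volume_parcellation(read_label_volume(p$parc(s, k)), k = k)
        })
        g <- coincidence_matrix(parcs, threshold = config$group_threshold)
        scheme <- group_scheme(
          g, k, derive_seed(config$master_seed, 100000 + k),
          parcs[[1]]$coords, parcs[[1]]$shape, config$n_restarts
        )
        write_label_volume(parcellation_volume(scheme, affine), p$scheme(k))
      }
    },
    "8" = {
      for (k in p$ks) {
        scheme <- volume_parcellation(read_label_volume(p$scheme(k)), k = k)
        for (s in p$subjects) {
          parc <- volume_parcellation(read_label_volume(p$parc(s, k)), k = k)
          rel <- apply_permutation(parc, match_labels(scheme, parc))
          write_label_volume(parcellation_volume(rel, affine), p$relabeled(s, k))
        }
      }
    },
    "9" = {
      for (k in p$ks) {
        rel <- lapply(p$subjects, function(s) {
          volume_parcellation(
            read_label_volume(p$relabeled(s, k)),
            k = k, allow_empty = TRUE
          )
        })
        pm <- probability_maps(rel)
        mpm <- maximum_probability_map(pm)
        write_maps(pm, mpm, p$group_dir, config$roi, affine)
      }
    },
    "10" = {
      for (k in p$ks) {
        mpm <- structure(
          list(
            volume = read_label_volume(p$mpm(k)),
            tie_broken = matrix(integer(0), 0, 3), k = k
          ),
          class = "mpm"
        )
        den <- remove_noise_voxels(mpm)
        write_label_volume(den$volume, p$mpm_denoised(k))
      }
    },
    "11" = {
      solutions <- lapply(p$subjects, function(s) {
        sols <- lapply(p$ks, function(k) {
          volume_parcellation(read_label_volume(p$parc(s, k)), k = k)
        })
        structure(stats::setNames(sols, paste0("k", p$ks)), class = "solution_set")
      })
      natives <- lapply(p$subjects, function(s) read_matrix(p$native[[s]]))
      val <- compute_validity(
        solutions, natives,
        n_reps = config$n_reps, seed = config$master_seed,
        group_threshold = config$group_threshold,
        n_restarts = config$n_restarts
      )
      write_validity_report(val, p$validity)
      utils::write.table(val$replicates, p$replicates,
        sep = "\t", row.names = FALSE, quote = FALSE
      )
    },
    "12" = {
      report <- read_validity_report(p$validity)
      sk <- suggest_k(report)
      writeLines(
        c(
          paste("suggested_k", sk$k),
          paste("votes", paste(sort(sk$votes$k), collapse = " "))
        ),
        p$suggestion
      )
      pl <- autoplot.parcellation_validity(
        structure(list(report = report), class = "parcellation_validity")
      )
      ggplot2::ggsave(p$plot, pl, width = 9, height = 6)
    },
    stop("unknown step ", step, call. = FALSE)
  )
  invisible(NULL)
}

#' Run the parcellation pipeline
#'
#' Executes the selected steps in order: 0 workspace, 2 seed-coordinate
#' extraction, 4 native and cross-correlation matrices, 5 clustering over
#' the k range, 7 group labeling scheme, 8 label propagation, 9
#' probabilistic maps and MPM, 10 noise-voxel removal, 11 validity
#' indices, 12 index report and plots. Steps 1, 3 and 6 are external
#' stages (registration, tractography, inverse warping) and are logged as
#' such. Steps whose outputs already validate are skipped, so the pipeline
#' is resumable; per-subject and per-k units derive their own RNG
#' substreams, so outputs are identical for any worker count.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run log: a tibble with one row per visited step
#'   (start time, elapsed seconds, host, status, message).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  init_workspace(config)
  p <- pipeline_paths(config)
  log_path <- file.path(p$log_dir, paste0(config$roi, "_run.log"))
  entries <- list()
  log_entry <- function(step, status, message, started, elapsed) {
    e <- tibble::tibble(
      step = step,
      start = format(started, "%Y-%m-%d %H:%M:%S"),
      elapsed_s = round(elapsed, 3), host = host_name(),
      status = status, message = message
    )
    cat(
      sprintf(
        "[%s] step %d on %s: %s (%.3fs) %s\n",
        e$start, step, e$host, status, elapsed, message
      ),
      file = log_path, append = TRUE
    )
    entries[[length(entries) + 1]] <<- e
  }

  for (step in sort(config$steps)) {
    started <- Sys.time()
    if (step %in% c(1, 3, 6)) {
      log_entry(
        step, "external",
        "external stage (registration/tractography); ingested inputs assumed",
        started, 0
      )
      next
    }
    if (step_outputs_ok(step, config, p) && step != 0) {
      log_entry(step, "skipped", "outputs already valid", started, 0)
      next
    }
    unmet <- unmet_dependency(step, config, p)
    if (!is.null(unmet)) {
      log_entry(
        step, "failed",
        paste("unmet dependency: step", unmet, "outputs missing"),
        started, 0
      )
      stop(
        "step ", step, " cannot run: outputs of step ", unmet, " are missing",
        call. = FALSE
      )
    }
    result <- tryCatch(
      {
        run_step(step, config, p)
        "ok"
      },
      error = function(e) conditionMessage(e)
    )
    elapsed <- as.numeric(difftime(Sys.time(), started, units = "secs"))
    if (identical(result, "ok")) {
      log_entry(step, "done", "", started, elapsed)
    } else {
      log_entry(step, "failed", result, started, elapsed)
      stop("step ", step, " failed: ", result, call. = FALSE)
    }
  }
  invisible(dplyr::bind_rows(entries))
}

#' Report step-by-step completion of a workspace
#'
#' Checks which pipeline steps have valid outputs (matrix files must
#' parse, not merely exist).
#'
#' @param config A [pipeline_config()].
#' @return Tibble with columns `step`, `kind` (`"internal"` or
#'   `"external"`), `complete`.
#' @export
pipeline_status <- function(config) {
  if (!dir.exists(roi_dir(config))) {
    stop("workspace not found: ", roi_dir(config), call. = FALSE)
  }
  p <- pipeline_paths(config)
  steps <- 0:12
  tibble::tibble(
    step = steps,
    kind = ifelse(steps %in% c(1, 3, 6), "external", "internal"),
    complete = vapply(
      steps,
      function(s) {
        if (s %in% c(1, 3, 6)) NA else step_outputs_ok(s, config, p)
      },
      logical(1)
    )
  )
}
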