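#' @importFrom rlang .data
NULL

#' Compute the full validity report over a range of k
#'
#' For every k this driver (i) pools the per-subject solutions into the
#' thresholded coincidence matrix and derives the group labeling scheme,
#' (ii) propagates the scheme back to each subject by optimal assignment,
#' (iii) builds the probabilistic maps and the noise-corrected maximum
#' probability map, and (iv) scores the solution: Cramer's V, Dice, NMI
#' and VI under the requested resampling schemes, the mean silhouette of
#' each subject's solution under the cosine distance of its native
#' connectivity matrix, the continuity of the group MPM under 6-, 18- and
#' 26-connectivity, and the hierarchy index between consecutive-k MPMs.
#'
#' @param solutions List (one per subject) of `solution_set`s sharing the
#'   same k range and seed set.
#' @param natives Optional list of per-subject native connectivity
#'   matrices (rows in seed order); required for the silhouette.
#' @param schemes Resampling schemes to run (subset of `"split_half"`,
#'   `"pairwise"`, `"leave_one_out"`).
#' @param n_reps Split-half repetitions (default 100).
#' @param seed Master seed for group clustering and the random splits.
#' @param group_threshold Coincidence-matrix threshold (default 0.5).
#' @param n_restarts k-means restarts for the group clustering.
#' @return Object of class `parcellation_validity`: list with `report`
#'   (tibble: index, scheme, k, mean, sd, n), `replicates` (raw replicate
#'   values), `group_schemes`, `relabeled`, and `mpms` (noise-corrected,
#'   per k).
#' @export
compute_validity <- function(solutions, natives = NULL,
                             schemes = c("split_half", "pairwise", "leave_one_out"),
                             n_reps = 100, seed = 1L, group_threshold = 0.5,
                             n_restarts = 100) {
  stopifnot(length(solutions) >= 1)
  ks <- sort(as.integer(sub("^k", "", names(solutions[[1]]))))
  n_subj <- length(solutions)
  replicates <- list()
  rows <- list()
  group_schemes <- list()
  relabeled_all <- list()
  mpms <- list()

  for (k in ks) {
    key <- paste0("k", k)
    parcs <- lapply(solutions, `[[`, key)
    g <- coincidence_matrix(parcs, threshold = group_threshold)
    scheme <- group_scheme(
      g, k, derive_seed(seed, 100000 + k),
      parcs[[1]]$coords, parcs[[1]]$shape, n_restarts
    )
    rel <- relabel_subjects(scheme, parcs)$parcellations
    group_schemes[[key]] <- scheme
    relabeled_all[[key]] <- rel

    reps_k <- list()
    if ("split_half" %in% schemes && n_subj >= 4) {
      reps_k$split_half <- split_half(rel, n_reps, derive_seed(seed, 200000 + k))
    }
    if ("pairwise" %in% schemes && n_subj >= 2) {
      reps_k$pairwise <- pairwise_indices(rel)
    }
    if ("leave_one_out" %in% schemes && n_subj >= 3) {
      reps_k$leave_one_out <- leave_one_out(rel)
    }
    if (length(reps_k) > 0) {
      replicates[[key]] <- dplyr::mutate(dplyr::bind_rows(reps_k), k = k)
    }

    if (!is.null(natives)) {
      svals <- vapply(seq_len(n_subj), function(s) {
        mean(silhouette_profile(natives[[s]], parcs[[s]])$s)
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        index = "silhouette", scheme = "individual", k = k,
        mean = mean(svals), sd = stats::sd(svals), n = n_subj
      )
    }

    mpm <- remove_noise_voxels(
      maximum_probability_map(probability_maps(rel))
    )
    mpms[[key]] <- mpm
    mp <- mpm_parcellation(mpm)
    for (conn in c(6, 18, 26)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        index = if (conn == 26) "continuity" else paste0("continuity_", conn),
        scheme = "mpm", k = k,
        mean = continuity_index(mp, conn), sd = NA_real_, n = 1L
      )
    }
  }

  for (k in ks[-1]) {
    pk <- mpm_parcellation(mpms[[paste0("k", k)]])
    pkm1 <- mpm_parcellation(mpms[[paste0("k", k - 1)]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      index = "hi", scheme = "mpm", k = k,
      mean = hierarchy_index(pk, pkm1), sd = NA_real_, n = 1L
    )
  }

  replicates <- dplyr::bind_rows(replicates)
  if (nrow(replicates) > 0) {
    summarized <- dplyr::summarise(
      dplyr::group_by(replicates, .data$index, .data$scheme, .data$k),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
    rows[[length(rows) + 1]] <- summarized
  }
  report <- dplyr::arrange(
    dplyr::bind_rows(rows),
    .data$index, .data$scheme, .data$k
  )
  structure(
    list(
      report = report, replicates = replicates,
      group_schemes = group_schemes, relabeled = relabeled_all,
      mpms = mpms, k_range = ks
    ),
    class = "parcellation_validity"
  )
}

#' @export
print.parcellation_validity <- function(x, ...) {
  cat(
    "<parcellation_validity> k =", min(x$k_range), "..", max(x$k_range),
    "over", length(x$relabeled[[1]]), "subjects\n"
  )
  print(x$report, n = 20)
  invisible(x)
}

#' @rdname tidy.parcellation
#' @export
tidy.parcellation_validity <- function(x, ...) x$report

#' Line plots of validity indices against k
#'
#' One panel per index: mean value against the candidate number of
#' subregions, one line per resampling scheme, with one-sd error bars
#' where replicates exist.
#'
#' @param object A `parcellation_validity` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parcellation_validity <- function(object, ...) {
  df <- object$report
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$k, y = .data$mean,
      colour = .data$scheme, group = .data$scheme
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(df$k)) +
    ggplot2::labs(
      x = "number of subregions k", y = "index value",
      colour = "scheme"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a validity report as a delimited table
#'
#' Tab-separated columns: index, scheme, k, mean, sd, n.
#'
#' @param validity A `parcellation_validity` object (or its report tibble).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_validity_report <- function(validity, path) {
  df <- if (inherits(validity, "parcellation_validity")) {
    validity$report
  } else {
    validity
  }
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_validity_report
#' @export
read_validity_report <- function(path) {
  tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  )
}
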