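#' Specification of a synthetic tractography cohort
#'
#' Describes a multi-subject phantom with planted subregions: every seed
#' voxel carries a whole-brain streamline-count profile drawn from its
#' subregion's prototype target pattern, contaminated with uniform noise,
#' optionally spatially jittered at subregion boundaries, and with
#' per-subject label permutations emulating the arbitrary label names of
#' clustering output.
#'
#' @param roi_shape Integer 3-vector: seed-region grid (every voxel is a
#'   seed). Default `c(6, 6, 8)`, i.e. 288 seed voxels.
#' @param k_true Planted number of subregions (>= 2).
#' @param n_subjects Number of subjects.
#' @param target_shape Integer 3-vector: whole-brain target grid.
#' @param n_samples Streamlines drawn per seed voxel (default 5000).
#' @param noise_mix Fraction in \[0, 1\] of streamline mass drawn uniformly
#'   over the target grid instead of from the prototype.
#' @param jitter Boundary perturbation radius in voxels (0 = none).
#' @param permute_labels Apply a random label permutation per subject.
#' @param voxel_size Voxel edge lengths in mm (shared by seed and target
#'   grids).
#' @param master_seed Integer master seed; the full cohort is a
#'   deterministic function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(roi_shape = c(6, 6, 8), k_true = 4, n_subjects = 20,
                         target_shape = c(16, 16, 16), n_samples = 5000,
                         noise_mix = 0.15, jitter = 0, permute_labels = TRUE,
                         voxel_size = c(2, 2, 2), master_seed = 1L) {
  stopifnot(
    length(roi_shape) == 3, all(roi_shape >= 1),
    length(target_shape) == 3, all(target_shape >= 1),
    k_true >= 2, n_subjects >= 1, n_samples >= 1,
    noise_mix >= 0, noise_mix <= 1, jitter >= 0
  )
  structure(
    list(
      roi_shape = as.integer(roi_shape), k_true = as.integer(k_true),
      n_subjects = as.integer(n_subjects),
      target_shape = as.integer(target_shape),
      n_samples = as.integer(n_samples), noise_mix = noise_mix,
      jitter = jitter, permute_labels = isTRUE(permute_labels),
      voxel_size = as.numeric(voxel_size),
      master_seed = as.integer(master_seed)
    ),
    class = "phantom_spec"
  )
}

# All ROI voxels in lexicographic (x, y, z) seed order, 0-based.
roi_grid_coords <- function(roi_shape) {
  g <- expand.grid(
    z = seq_len(roi_shape[3]) - 1L,
    y = seq_len(roi_shape[2]) - 1L,
    x = seq_len(roi_shape[1]) - 1L
  )
  tibble::tibble(
    x = as.integer(g$x), y = as.integer(g$y), z = as.integer(g$z)
  )
}

# Canonical planted truth: near-equal slabs along the longest ROI axis.
planted_truth <- function(spec) {
  coords <- roi_grid_coords(spec$roi_shape)
  axis <- which.max(spec$roi_shape)
  pos <- as.matrix(coords)[, axis]
  labels <- as.integer(
    pmin(floor(pos * spec$k_true / spec$roi_shape[axis]) + 1, spec$k_true)
  )
  parcellation(labels, coords, spec$roi_shape, k = spec$k_true)
}

#' Prototype target patterns for the planted subregions
#'
#' One probability vector over the target grid per planted subregion, with
#' disjoint supports (pairwise cosine similarity 0, comfortably below the
#' 0.2 design bound) and sparse, uneven within-support weights.
#'
#' @param spec A [phantom_spec()].
#' @return A `k_true` x `prod(target_shape)` matrix; rows sum to 1.
#' @export
make_prototypes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_target <- prod(spec$target_shape)
  block <- n_target %/% spec$k_true
  if (block < 8) {
    stop(
      "target grid too small to place ", spec$k_true,
      " disjoint prototype patterns",
      call. = FALSE
    )
  }
  with_seed(derive_seed(spec$master_seed, 0), {
    proto <- matrix(0, spec$k_true, n_target)
    for (c in seq_len(spec$k_true)) {
      idx <- ((c - 1) * block + 1):(c * block)
      support <- sort(sample(idx, max(4, round(0.4 * block))))
      w <- stats::rgamma(length(support), shape = 1.5)
      proto[c, support] <- w / sum(w)
    }
    proto
  })
}

# Jitter: voxels within `radius` (Chebyshev) of a differently-labeled voxel
# flip, with probability 0.5, to the label of a random such neighbor.
jitter_labels <- function(labels, coords, radius) {
  if (radius <= 0) {
    return(labels)
  }
  m <- as.matrix(coords)
  n <- nrow(m)
  out <- labels
  r <- ceiling(radius)
  key <- function(v) paste(v[, 1], v[, 2], v[, 3])
  lookup <- stats::setNames(labels, key(m))
  offsets <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  for (i in seq_len(n)) {
    nb <- m[rep(i, nrow(offsets)), , drop = FALSE] + offsets
    nb_lab <- lookup[key(nb)]
    nb_lab <- nb_lab[!is.na(nb_lab) & nb_lab != labels[i]]
    if (length(nb_lab) > 0 && stats::runif(1) < 0.5) {
      out[i] <- nb_lab[sample.int(length(nb_lab), 1)]
    }
  }
  out
}

#' Simulate a phantom cohort
#'
#' For each subject and seed voxel with planted label c, the streamline
#' counts over the target grid are one multinomial draw of `n_samples`
#' trials from `(1 - noise_mix) * prototype_c + noise_mix * uniform`.
#' Subjects use independent RNG substreams derived from the master seed, so
#' the cohort is reproducible bit-for-bit and insensitive to the order in
#' which subjects are generated.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_cohort`: list with elements
#'   `spec`, `coords` (seed order), `canonical` (group-truth
#'   [parcellation()]), `profiles` (per-subject seed x target count
#'   matrices), `truth` (per-subject planted parcellations, after jitter
#'   and permutation), and `permutations` (the applied label bijections).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  canonical <- planted_truth(spec)
  coords <- roi_grid_coords(spec$roi_shape)
  proto <- make_prototypes(spec)
  n_target <- prod(spec$target_shape)
  uniform <- rep(1 / n_target, n_target)
  n_seed <- nrow(coords)

  profiles <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  permutations <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    with_seed(derive_seed(spec$master_seed, s), {
      lab <- jitter_labels(canonical$labels, coords, spec$jitter)
      mix <- (1 - spec$noise_mix) * proto +
        spec$noise_mix * matrix(uniform, spec$k_true, n_target, byrow = TRUE)
      counts <- matrix(0L, n_seed, n_target)
      for (c in seq_len(spec$k_true)) {
        rows <- which(lab == c)
        if (length(rows) > 0) {
          draws <- stats::rmultinom(length(rows), spec$n_samples, mix[c, ])
          counts[rows, ] <- t(draws)
        }
      }
      perm <- if (spec$permute_labels) {
        sample.int(spec$k_true)
      } else {
        seq_len(spec$k_true)
      }
      profiles[[s]] <- counts
      truth[[s]] <- parcellation(
        perm[lab], coords, spec$roi_shape,
        k = spec$k_true, allow_empty = TRUE
      )
      permutations[[s]] <- perm
    })
  }
  structure(
    list(
      spec = spec, coords = coords, canonical = canonical,
      profiles = profiles, truth = truth, permutations = permutations
    ),
    class = "phantom_cohort"
  )
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(
    "<phantom_cohort> ", x$spec$n_subjects, " subjects, ",
    nrow(x$coords), " seed voxels, k_true = ", x$spec$k_true,
    ", noise_mix = ", x$spec$noise_mix, "\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a bilateral (left/right) phantom cohort
#'
#' The right-hemisphere cohort shares the planted topological arrangement
#' of the left, mirrored across the mid-sagittal plane, with independent
#' multinomial noise. The contact structure of the two planted truths is
#' therefore identical, so their topological distance is 0.
#'
#' @param spec A [phantom_spec()] (used for the left hemisphere; the right
#'   uses an independently derived master seed).
#' @return List with elements `left` and `right`, both `phantom_cohort`s;
#'   right-hemisphere coordinates are mirrored along x.
#' @export
simulate_bilateral_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  left <- simulate_cohort(spec)
  rspec <- spec
  rspec$master_seed <- derive_seed(spec$master_seed, 104729)
  right <- simulate_cohort(rspec)
  right$canonical <- mirror_parcellation(right$canonical)
  right$truth <- lapply(right$truth, mirror_parcellation)
  list(left = left, right = right)
}

#' Write a phantom cohort in the pipeline's ingestion layout
#'
#' Emits the ROI mask as NIfTI, one streamline-count matrix per subject in
#' the delimited-matrix layout, a truth sidecar (one label column per
#' subject, rows in seed order), and a metadata file with the target-grid
#' geometry.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @param roi ROI name used in file names.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, roi = "roi") {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  mask <- label_volume(
    array(1L, spec$roi_shape),
    diag(c(spec$voxel_size, 1))
  )
  write_label_volume(mask, file.path(dir, paste0(roi, "_mask.nii.gz")))
  subjects <- sprintf("sub%03d", seq_len(spec$n_subjects))
  for (s in seq_along(subjects)) {
    sdir <- file.path(dir, subjects[s])
    dir.create(sdir, showWarnings = FALSE)
    write_matrix(
      cohort$profiles[[s]],
      file.path(sdir, paste0(roi, "_profile.txt"))
    )
  }
  truth <- vapply(cohort$truth, function(p) p$labels, integer(nrow(cohort$coords)))
  utils::write.table(
    truth,
    file.path(dir, paste0(roi, "_truth.txt")),
    row.names = FALSE, col.names = subjects, quote = FALSE
  )
  yaml::write_yaml(
    list(
      roi = roi, subjects = subjects,
      roi_shape = spec$roi_shape, target_shape = spec$target_shape,
      voxel_size = spec$voxel_size, n_samples = spec$n_samples,
      k_true = spec$k_true
    ),
    file.path(dir, paste0(roi, "_meta.yaml"))
  )
  invisible(dir)
}
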