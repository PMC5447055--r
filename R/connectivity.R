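#' Threshold a connectivity profile
#'
#' Streamline counts whose implied connection probability (count divided by
#' the number of samples drawn) does not exceed `p_min` are set to zero.
#' The default cutoff is p > 0.04%, i.e. a count of 2 out of 5000 samples
#' is removed and 3 is retained; the inequality is strict. Thresholding
#' raw counts removes spurious low-probability connections while keeping
#' sensitivity to genuine pathways.
#'
#' @param counts Non-negative numeric vector of streamline counts over the
#'   target grid.
#' @param p_min Probability cutoff (default 0.0004, i.e. 0.04%).
#' @param n_samples Streamlines drawn per seed voxel (default 5000).
#' @return The thresholded count vector.
#' @export
threshold_profile <- function(counts, p_min = 0.0004, n_samples = 5000) {
  if (any(counts < 0)) stop("negative streamline counts", call. = FALSE)
  stopifnot(p_min >= 0, p_min < 1)
  counts[counts / n_samples <= p_min] <- 0
  counts
}

# Voxel-center coordinates (mm) for every cell of a grid, in R's
# column-major linear order (x fastest).
target_centers_mm <- function(target_shape, voxel_size) {
  idx <- arrayInd(seq_len(prod(target_shape)), target_shape) - 1L
  sweep(idx + 0.5, 2, voxel_size, `*`)
}

#' Correct a profile for path-length bias
#'
#' Probabilistic tractography visits near targets more often than far ones;
#' each retained count is multiplied by the Euclidean distance (mm) between
#' the target-voxel center and the seed-voxel center. The seed's own voxel
#' sits at distance 0 and is zeroed.
#'
#' @param counts Numeric count vector over the target grid (column-major
#'   order, x fastest).
#' @param seed_coord 0-based voxel triple of the seed.
#' @param target_shape Integer 3-vector: target grid extent.
#' @param voxel_size Voxel edge lengths in mm.
#' @return The distance-weighted profile (real-valued).
#' @export
distance_correct <- function(counts, seed_coord, target_shape,
                             voxel_size = c(2, 2, 2)) {
  centers <- target_centers_mm(target_shape, voxel_size)
  seed_mm <- (as.numeric(seed_coord) + 0.5) * voxel_size
  d <- sqrt(
    (centers[, 1] - seed_mm[1])^2 +
      (centers[, 2] - seed_mm[2])^2 +
      (centers[, 3] - seed_mm[3])^2
  )
  counts * d
}

# Block id (1-based, column-major over the block grid) for every target
# voxel when the grid is cut into axis-aligned cubes of block_mm.
block_assignment <- function(target_shape, voxel_size, block_mm) {
  f <- block_mm / voxel_size
  if (any(f < 1)) {
    stop("block_mm must not be smaller than the native voxel size", call. = FALSE)
  }
  if (any(abs(f - round(f)) > 1e-8)) {
    stop("block_mm must be a positive multiple of the native voxel size",
      call. = FALSE
    )
  }
  f <- round(f)
  idx <- arrayInd(seq_len(prod(target_shape)), target_shape) - 1L
  bidx <- sweep(idx, 2, f, `%/%`)
  nblocks <- ceiling(target_shape / f)
  list(
    id = 1L + bidx[, 1] + nblocks[1] * (bidx[, 2] + nblocks[2] * bidx[, 3]),
    n = prod(nblocks), nblocks = nblocks
  )
}

#' Down-sample a profile to coarse blocks
#'
#' Partitions the target grid into axis-aligned blocks of `block_mm` per
#' side (default 5 mm) and sums the member entries, so total streamline
#' mass is conserved exactly.
#'
#' @inheritParams distance_correct
#' @param block_mm Block edge length in mm; must be a positive multiple of
#'   the native voxel size.
#' @return Numeric vector of block values.
#' @export
downsample_profile <- function(counts, target_shape, voxel_size = c(2, 2, 2),
                               block_mm = 5) {
  ba <- block_assignment(target_shape, voxel_size, block_mm)
  out <- numeric(ba$n)
  agg <- rowsum(counts, ba$id)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Build the native connectivity matrix for a seed region
#'
#' Stacks the processed connectivity profile of every seed voxel, in seed
#' order, into one matrix: rows are seed voxels, columns are down-sampled
#' target blocks. Processing order per profile is fixed: threshold the raw
#' counts (the cutoff is expressed in raw samples), then correct for path
#' length, then down-sample.
#'
#' @param profiles Matrix of raw counts, one row per seed voxel in the
#'   order of `coords`, columns over the target grid (column-major).
#' @param coords Seed coordinates (tibble/matrix with x, y, z; 0-based),
#'   row i matching row i of `profiles`.
#' @inheritParams distance_correct
#' @param threshold_p Probability cutoff (default 0.0004).
#' @param n_samples Streamlines per seed voxel (default 5000).
#' @param block_mm Down-sampling block size in mm (default 5).
#' @return Numeric matrix, `nrow(coords)` x number of blocks.
#' @export
build_native_matrix <- function(profiles, coords, target_shape,
                                voxel_size = c(2, 2, 2), threshold_p = 0.0004,
                                n_samples = 5000, block_mm = 5) {
  coords <- as.matrix(as.data.frame(coords)[, 1:3])
  if (nrow(profiles) != nrow(coords)) {
    stop("one profile row per seed voxel required", call. = FALSE)
  }
  if (ncol(profiles) != prod(target_shape)) {
    stop("profile length does not match the target grid", call. = FALSE)
  }
  if (any(profiles < 0)) stop("negative streamline counts", call. = FALSE)
  m <- profiles
  m[m / n_samples <= threshold_p] <- 0
  centers <- target_centers_mm(target_shape, voxel_size)
  ba <- block_assignment(target_shape, voxel_size, block_mm)
  out <- matrix(0, nrow(m), ba$n)
  for (i in seq_len(nrow(m))) {
    seed_mm <- (as.numeric(coords[i, ]) + 0.5) * voxel_size
    d <- sqrt(
      (centers[, 1] - seed_mm[1])^2 +
        (centers[, 2] - seed_mm[2])^2 +
        (centers[, 3] - seed_mm[3])^2
    )
    agg <- rowsum(m[i, ] * d, ba$id)
    out[i, as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Cross-correlation matrix between seed profiles
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the
#' native connectivity matrix. Rows with zero variance get correlation 0
#' with every other row and 1 with themselves, keeping the matrix usable
#' without undefined divisions.
#'
#' @param native Native connectivity matrix (seed voxels x target blocks).
#' @return Square symmetric matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @export
cross_correlation <- function(native) {
  if (nrow(native) < 2) {
    stop("at least two seed profiles are required", call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(t(native)))
  cc[is.na(cc)] <- 0
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}
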