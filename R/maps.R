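#' Cross-subject probabilistic maps
#'
#' One real-valued volume per cluster; the value at a voxel is the number
#' of subjects assigning that voxel to the cluster divided by the total
#' number of subjects (all subjects, whether or not they cover the voxel).
#' High values mean low inter-individual variability of the subregion.
#'
#' @param parcellations List of relabeled [parcellation()]s on a common
#'   grid with consistent labels.
#' @return Object of class `probability_maps`: list with `maps` (one 3D
#'   array per cluster), `k`, `shape`, `n_subjects`.
#' @export
probability_maps <- function(parcellations) {
  if (length(parcellations) == 0) {
    stop("at least one subject is required", call. = FALSE)
  }
  k <- parcellations[[1]]$k
  shape <- parcellations[[1]]$shape
  for (p in parcellations) {
    if (p$k != k || !identical(p$shape, shape)) {
      stop("parcellations must share k and grid", call. = FALSE)
    }
  }
  n <- length(parcellations)
  maps <- lapply(seq_len(k), function(c) array(0, shape))
  for (p in parcellations) {
    for (c in seq_len(k)) {
      sel <- p$labels == c
      if (any(sel)) {
        idx <- p$coords[sel, , drop = FALSE] + 1L
        maps[[c]][idx] <- maps[[c]][idx] + 1
      }
    }
  }
  maps <- lapply(maps, function(m) m / n)
  structure(
    list(maps = maps, k = k, shape = shape, n_subjects = n),
    class = "probability_maps"
  )
}

# 26-neighborhood offsets (center excluded).
neighbor_offsets <- function(connectivity = 26) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(o)) == 1,
    "18" = rowSums(abs(o)) <= 2,
    "26" = rep(TRUE, nrow(o)),
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  )
  o[keep, , drop = FALSE]
}

# Mean of `vol` over the 26 neighbors of voxel (1-based index triple);
# out-of-volume neighbors contribute 0 and the divisor stays 26.
neighbor_mean26 <- function(vol, idx, offsets) {
  nb <- sweep(offsets, 2, idx, `+`)
  inside <- nb[, 1] >= 1 & nb[, 1] <= dim(vol)[1] &
    nb[, 2] >= 1 & nb[, 2] <= dim(vol)[2] &
    nb[, 3] >= 1 & nb[, 3] <= dim(vol)[3]
  sum(vol[nb[inside, , drop = FALSE]]) / 26
}

#' Maximum probability map
#'
#' Assigns every voxel with any nonzero cluster probability to the cluster
#' of highest probability. Where two or more clusters tie at the maximum,
#' each tied cluster's probability is averaged over the 26 directly
#' adjacent voxels and the larger average wins; a residual tie goes to the
#' smallest label. Tie-broken voxels are recorded.
#'
#' @param pm A [probability_maps()] object.
#' @return Object of class `mpm`: list with `volume` (a [label_volume()]),
#'   `tie_broken` (0-based coordinates that needed the neighborhood rule),
#'   and `k`.
#' @export
maximum_probability_map <- function(pm) {
  stopifnot(inherits(pm, "probability_maps"))
  shape <- pm$shape
  k <- pm$k
  flat <- vapply(pm$maps, as.vector, numeric(prod(shape)))
  if (k == 1) flat <- matrix(flat, ncol = 1)
  maxp <- do.call(pmax, as.data.frame(flat))
  labels <- max.col(flat, ties.method = "first")
  labels[maxp <= 0] <- 0L
  n_at_max <- rowSums(flat >= maxp - 1e-15 & maxp > 0)
  tie_idx <- which(n_at_max >= 2 & maxp > 0)
  offsets <- neighbor_offsets(26)
  for (v in tie_idx) {
    idx <- arrayInd(v, shape)
    tied <- which(flat[v, ] >= maxp[v] - 1e-15)
    avgs <- vapply(
      tied,
      function(c) neighbor_mean26(pm$maps[[c]], idx[1, ], offsets),
      numeric(1)
    )
    labels[v] <- tied[which.max(avgs)] # which.max: smallest index on ties
  }
  out <- array(as.integer(labels), shape)
  tb <- if (length(tie_idx) > 0) {
    arrayInd(tie_idx, shape) - 1L
  } else {
    matrix(integer(0), 0, 3)
  }
  colnames(tb) <- c("x", "y", "z")
  structure(
    list(volume = label_volume(out), tie_broken = tb, k = k),
    class = "mpm"
  )
}

#' @export
print.mpm <- function(x, ...) {
  cat(
    "<mpm> ", sum(x$volume$data != 0), " labeled voxels, k = ", x$k,
    ", ", nrow(x$tie_broken), " tie-broken\n",
    sep = ""
  )
  invisible(x)
}

#' Correct noisy voxels in a maximum probability map
#'
#' A labeled voxel whose label differs from the strict-majority label of
#' its labeled 6-connected neighbors is flipped to that majority; voxels
#' with ties or no labeled neighbors are left alone, and background never
#' gains a label. Passes repeat (synchronously) until no voxel changes or
#' `max_iter` passes have run.
#'
#' @param mpm An [maximum_probability_map()] result.
#' @param max_iter Pass cap (default 10).
#' @return The corrected `mpm`; the number of passes used is stored in
#'   attribute `"iterations"`.
#' @export
remove_noise_voxels <- function(mpm, max_iter = 10) {
  stopifnot(inherits(mpm, "mpm"))
  vol <- mpm$volume$data
  shape <- dim(vol)
  offsets <- neighbor_offsets(6)
  iterations <- 0
  for (pass in seq_len(max_iter)) {
    labeled <- which(vol != 0)
    if (length(labeled) == 0) break
    new <- vol
    changed <- FALSE
    coords <- arrayInd(labeled, shape)
    for (i in seq_along(labeled)) {
      nb <- sweep(offsets, 2, coords[i, ], `+`)
      inside <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nl <- vol[nb[inside, , drop = FALSE]]
      nl <- nl[nl != 0]
      if (length(nl) == 0) next
      tab <- tabulate(nl, mpm$k)
      top <- max(tab)
      if (top * 2 > length(nl)) {
        maj <- which.max(tab)
        if (maj != vol[labeled[i]]) {
          new[labeled[i]] <- maj
          changed <- TRUE
        }
      }
    }
    vol <- new
    iterations <- pass
    if (!changed) break
  }
  out <- structure(
    list(
      volume = label_volume(vol, mpm$volume$affine),
      tie_broken = mpm$tie_broken, k = mpm$k
    ),
    class = "mpm"
  )
  attr(out, "iterations") <- iterations
  out
}

#' Lift an MPM into a parcellation over its labeled voxels
#'
#' @param mpm An `mpm` object.
#' @return A [parcellation()] (empty clusters allowed: a subregion can
#'   vanish from a group map).
#' @export
mpm_parcellation <- function(mpm) {
  stopifnot(inherits(mpm, "mpm"))
  volume_parcellation(mpm$volume, k = mpm$k, allow_empty = TRUE)
}

#' Write probability maps and an MPM to disk
#'
#' Probability maps are written as one 32-bit float NIfTI per cluster
#' (`<roi>_k<k>_c<label>_pm.nii.gz`), the MPM as an integer NIfTI, and the
#' tie-break provenance as a plain-text sidecar.
#'
#' @param pm A [probability_maps()] object.
#' @param mpm An `mpm` object.
#' @param dir Output directory.
#' @param roi ROI name for the file-name pattern.
#' @param affine Voxel-to-world transform.
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(pm, mpm, dir, roi = "roi", affine = diag(4)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (c in seq_len(pm$k)) {
    p <- file.path(dir, sprintf("%s_k%d_c%d_pm.nii.gz", roi, pm$k, c))
    write_probability_volume(pm$maps[[c]], p, affine)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, sprintf("%s_k%d_mpm.nii.gz", roi, pm$k))
  write_label_volume(
    label_volume(mpm$volume$data, affine), mp
  )
  tb <- file.path(dir, sprintf("%s_k%d_mpm_ties.txt", roi, pm$k))
  write_seed_coordinates(as.data.frame(mpm$tie_broken), tb)
  invisible(c(paths, mp, tb))
}
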