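#' Parcellation of a seed region
#'
#' Assignment of each seed voxel to a subregion label in 1..k, tied to a
#' fixed voxel grid. Labels of a freshly clustered parcellation are
#' arbitrary names; cross-subject meaning is only established by the
#' group-labeling stage.
#'
#' @param labels Integer vector of labels in 1..k, one per seed voxel.
#' @param coords Matrix or data frame of 0-based voxel coordinates
#'   (columns x, y, z), row i matching `labels[i]`.
#' @param shape Integer 3-vector: the voxel grid extent.
#' @param k Number of clusters; defaults to `max(labels)`.
#' @param allow_empty Permit labels in 1..k with no voxels (needed for
#'   group maps where a subregion can vanish from one half-cohort).
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, coords, shape, k = max(labels),
                         allow_empty = FALSE) {
  coords <- as.matrix(as.data.frame(coords)[, 1:3])
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y", "z")
  labels <- as.integer(labels)
  if (length(labels) != nrow(coords)) {
    stop("one label per coordinate required", call. = FALSE)
  }
  if (any(labels < 1L) || any(labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  if (!allow_empty && length(unique(labels)) < k) {
    stop("every cluster 1..k must be non-empty", call. = FALSE)
  }
  if (any(coords < 0L) || any(coords >= matrix(shape, nrow(coords), 3, byrow = TRUE))) {
    stop("coordinates fall outside the grid", call. = FALSE)
  }
  structure(
    list(
      labels = labels, coords = coords,
      shape = as.integer(shape), k = as.integer(k)
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(
    "<parcellation> ", length(x$labels), " voxels in ", x$k,
    " clusters on a ", paste(x$shape, collapse = "x"), " grid\n",
    sep = ""
  )
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parcellation into a voxel table
#'
#' @param x A [parcellation()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z` (0-based voxel indices) and
#'   `label`.
#' @export
tidy.parcellation <- function(x, ...) {
  tibble::tibble(
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
    label = x$labels
  )
}

#' @rdname tidy.parcellation
#' @return For `glance()`: a one-row tibble with `k`, `n_voxels`, and the
#'   smallest and largest cluster size.
#' @export
glance.parcellation <- function(x, ...) {
  sizes <- tabulate(x$labels, x$k)
  tibble::tibble(
    k = x$k, n_voxels = length(x$labels),
    min_cluster = min(sizes), max_cluster = max(sizes)
  )
}

#' Convert between parcellations and label volumes
#'
#' `parcellation_volume()` paints the labels into a 3D [label_volume()];
#' `volume_parcellation()` lifts the non-zero voxels of a label volume back
#' into a [parcellation()] (in seed-coordinate order).
#'
#' @param p A [parcellation()].
#' @param affine Voxel-to-world transform for the output volume.
#' @return A [label_volume()] / a [parcellation()].
#' @export
parcellation_volume <- function(p, affine = diag(4)) {
  stopifnot(inherits(p, "parcellation"))
  arr <- array(0L, dim = p$shape)
  arr[p$coords + 1L] <- p$labels
  label_volume(arr, affine)
}

#' @rdname parcellation_volume
#' @param vol A [label_volume()].
#' @param k Cluster count; defaults to the largest label present.
#' @param allow_empty Passed to [parcellation()].
#' @export
volume_parcellation <- function(vol, k = NULL, allow_empty = FALSE) {
  stopifnot(inherits(vol, "label_volume"))
  coords <- extract_seed_coordinates(vol)
  labels <- vol$data[as.matrix(coords) + 1L]
  parcellation(
    labels, coords, dim(vol$data),
    k = k %||% max(labels), allow_empty = allow_empty
  )
}

#' Relabel clusters canonically
#'
#' Renumbers labels 1..k by decreasing cluster size, breaking ties by the
#' smallest voxel index contained in the cluster. Makes clustering output
#' reproducible across eigen-solver sign flips and restart order.
#'
#' @param p A [parcellation()].
#' @return A [parcellation()] with the same partition, canonical names.
#' @export
canonicalize_labels <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  sizes <- tabulate(p$labels, p$k)
  first_voxel <- vapply(
    seq_len(p$k),
    function(l) {
      w <- which(p$labels == l)
      if (length(w) == 0) .Machine$integer.max else min(w)
    },
    integer(1)
  )
  ord <- order(-sizes, first_voxel)
  remap <- integer(p$k)
  remap[ord] <- seq_len(p$k)
  parcellation(
    remap[p$labels], p$coords, p$shape,
    k = p$k, allow_empty = any(sizes == 0)
  )
}

#' Apply a label permutation
#'
#' @param p A [parcellation()].
#' @param perm Integer vector of length k: voxels labeled `j` become
#'   `perm[j]`. Must be a bijection of 1..k.
#' @return The relabeled [parcellation()]; the partition is unchanged.
#' @export
apply_permutation <- function(p, perm) {
  stopifnot(inherits(p, "parcellation"))
  if (length(perm) != p$k || !setequal(perm, seq_len(p$k))) {
    stop("`perm` must be a bijection of 1..k", call. = FALSE)
  }
  parcellation(
    perm[p$labels], p$coords, p$shape,
    k = p$k, allow_empty = length(unique(p$labels)) < p$k
  )
}

#' Mirror a parcellation across the mid-sagittal plane
#'
#' Flips the first voxel axis about the grid midplane; used to map a
#' right-hemisphere grid onto the left before hemispheric label
#' harmonization.
#'
#' @param p A [parcellation()].
#' @return The mirrored [parcellation()].
#' @export
mirror_parcellation <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  coords <- p$coords
  coords[, 1] <- p$shape[1] - 1L - coords[, 1]
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  parcellation(
    p$labels[ord], coords[ord, , drop = FALSE], p$shape,
    k = p$k, allow_empty = length(unique(p$labels)) < p$k
  )
}
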