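#' Group-level label-coincidence matrix
#'
#' Entry (i, j) is the fraction of subjects in which seed voxels i and j
#' carry the same cluster label; entries below `threshold` are zeroed.
#' This pooled similarity drives the group-level clustering that resolves
#' the arbitrary label names of per-subject solutions.
#'
#' @param parcellations List of per-subject [parcellation()]s on a shared
#'   seed set with a shared k.
#' @param threshold Zeroing threshold (default 0.5: a voxel pair must
#'   co-label in a majority of subjects).
#' @return Square symmetric matrix with entries in \[0, 1\].
#' @export
coincidence_matrix <- function(parcellations, threshold = 0.5) {
  stopifnot(length(parcellations) >= 1)
  check_shared_seed_set(parcellations)
  n <- length(parcellations[[1]]$labels)
  acc <- matrix(0, n, n)
  for (p in parcellations) {
    acc <- acc + outer(p$labels, p$labels, `==`)
  }
  g <- acc / length(parcellations)
  g[g < threshold] <- 0
  g
}

check_shared_seed_set <- function(parcellations) {
  ref <- parcellations[[1]]
  for (p in parcellations[-1]) {
    if (!identical(p$coords, ref$coords) || !identical(p$shape, ref$shape)) {
      stop("parcellations do not share a seed set", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Group labeling scheme from the coincidence matrix
#'
#' Applies normalized-cut spectral clustering to the thresholded
#' coincidence matrix, yielding a group-level reference labeling that each
#' subject is then matched to.
#'
#' @param g Coincidence matrix from [coincidence_matrix()].
#' @inheritParams spectral_cluster
#' @return A [parcellation()].
#' @export
group_scheme <- function(g, k, seed, coords, shape, n_restarts = 100) {
  w <- g
  diag(w) <- 0
  spectral_cluster(w, k, seed, coords, shape, n_restarts)
}

# k x k overlap-count matrix over voxels present (and labeled) in both
# parcellations: O[r, t] = #{voxels with reference label r and target t}.
overlap_counts <- function(reference, target) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  tl <- stats::setNames(target$labels, key(target$coords))
  rl <- tl[key(reference$coords)]
  keep <- !is.na(rl)
  k <- reference$k
  o <- matrix(0, k, k)
  if (any(keep)) {
    tab <- table(
      factor(reference$labels[keep], levels = seq_len(k)),
      factor(rl[keep], levels = seq_len(k))
    )
    o <- matrix(as.numeric(tab), k, k)
  }
  o
}

# Maximum-weight bijection of 1..k by exact dynamic programming over label
# subsets (k <= ~16); among equally optimal assignments the
# lexicographically smallest mapping (perm[1], ..., perm[k]) is returned.
assignment_permutation <- function(o) {
  k <- nrow(o)
  stopifnot(ncol(o) == k, k >= 1)
  if (k > 16) stop("assignment supports at most 16 labels", call. = FALSE)
  n_masks <- bitwShiftL(1L, k)
  pc <- integer(n_masks)
  for (b in seq_len(k) - 1L) {
    pc <- pc + bitwAnd(bitwShiftR(0:(n_masks - 1L), b), 1L)
  }
  g <- rep(-Inf, n_masks)
  g[1] <- 0
  for (m in order(pc)[-1]) {
    mask <- m - 1L
    t <- k - pc[m] + 1L
    for (r in seq_len(k)) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(mask, bit) != 0L) {
        cand <- o[r, t] + g[bitwXor(mask, bit) + 1L]
        if (cand > g[m]) g[m] <- cand
      }
    }
  }
  perm <- integer(k)
  avail <- n_masks - 1L
  tol <- 1e-9
  for (t in seq_len(k)) {
    for (r in seq_len(k)) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(avail, bit) != 0L) {
        rest <- bitwXor(avail, bit)
        if (abs(o[r, t] + g[rest + 1L] - g[avail + 1L]) <= tol) {
          perm[t] <- r
          avail <- rest
          break
        }
      }
    }
  }
  perm
}

#' Match the labels of one parcellation to a reference
#'
#' Builds the k x k overlap-count matrix between reference and target
#' labels and returns the bijection of 1..k that maximizes total spatial
#' overlap (optimal linear assignment). Among equally optimal bijections
#' the lexicographically smallest mapping is returned, which makes the
#' matching deterministic.
#'
#' @param reference,target [parcellation()]s with the same k (seed sets
#'   may differ; overlap is counted on the common voxels).
#' @return Integer vector `perm` of length k: target label j corresponds
#'   to reference label `perm[j]`; apply with [apply_permutation()].
#' @export
match_labels <- function(reference, target) {
  stopifnot(inherits(reference, "parcellation"), inherits(target, "parcellation"))
  if (reference$k != target$k) {
    stop("parcellations must have the same k to be matched", call. = FALSE)
  }
  o <- overlap_counts(reference, target)
  # o[r, t]: rows reference, cols target; assign each target label a
  # reference label.
  assignment_permutation(o)
}

#' Propagate a group labeling scheme to each subject
#'
#' Each subject's labels are passed through the overlap-maximizing
#' bijection against the scheme, so corresponding subregions share a name
#' across subjects. The partition of every subject is unchanged.
#'
#' @param scheme Group-level reference [parcellation()].
#' @param parcellations List of per-subject [parcellation()]s, same k.
#' @return List with `parcellations` (relabeled) and `permutations` (the
#'   applied bijections).
#' @export
relabel_subjects <- function(scheme, parcellations) {
  perms <- lapply(parcellations, function(p) match_labels(scheme, p))
  relabeled <- mapply(
    function(p, perm) apply_permutation(p, perm),
    parcellations, perms,
    SIMPLIFY = FALSE
  )
  list(parcellations = relabeled, permutations = perms)
}

#' Harmonize cluster labels across hemispheres
#'
#' Mirrors the right-hemisphere parcellation across the mid-sagittal plane
#' (flip of the first voxel axis about the grid midplane), matches its
#' labels to the left hemisphere by optimal assignment, and returns the
#' right parcellation with the matched labels. If the mirrored supports do
#' not overlap at all, a warning is issued and the labels are left
#' unchanged.
#'
#' @param left,right [parcellation()]s with the same k.
#' @return The relabeled right [parcellation()], with the applied
#'   bijection in attribute `"permutation"`.
#' @export
harmonize_hemispheres <- function(left, right) {
  if (left$k != right$k) {
    stop("hemispheres must have the same k", call. = FALSE)
  }
  mirrored <- mirror_parcellation(right)
  o <- overlap_counts(left, mirrored)
  if (sum(o) == 0) {
    warning("mirrored hemispheres share no voxels; labels left unchanged")
    perm <- seq_len(right$k)
  } else {
    perm <- assignment_permutation(o)
  }
  out <- apply_permutation(right, perm)
  attr(out, "permutation") <- perm
  out
}
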