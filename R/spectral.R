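#' Affinity matrix from a cross-correlation matrix
#'
#' Normalized-cut clustering needs non-negative edge weights: negative
#' correlations are clipped to zero (anti-correlated profiles carry no
#' affinity) rather than shifted, and the diagonal is zeroed.
#'
#' @param cc Square symmetric correlation matrix.
#' @return Symmetric non-negative affinity matrix with zero diagonal.
#' @export
affinity_from_correlation <- function(cc) {
  stopifnot(is.matrix(cc), nrow(cc) == ncol(cc))
  w <- pmax(cc, 0)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    dn <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  x[centers, , drop = FALSE]
}

# Repeated k-means with k-means++ seeding; returns the labeling with the
# lowest within-cluster sum of squares over n_restarts runs. Errors if no
# restart yields k non-empty clusters.
kmeans_restarts <- function(x, k, n_restarts) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers + matrix(stats::rnorm(length(centers), sd = 1e-10),
      nrow(centers), ncol(centers)
    )
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) {
      best <- fit
    }
  }
  best
}

#' Normalized-cut spectral clustering of seed voxels
#'
#' The symmetric-normalization spectral procedure: with affinity W and
#' degree matrix D, the top-k eigenvectors of D^(-1/2) W D^(-1/2) are
#' stacked, their rows normalized to unit length, and clustered with
#' k-means (k-means++ seeding, 100 restarts). No spatial constraint is
#' applied. Output labels are renumbered canonically (decreasing cluster
#' size, ties by smallest voxel index), so the result is deterministic
#' given `(W, k, seed)`.
#'
#' @param w Symmetric non-negative affinity matrix over the seed voxels.
#' @param k Number of clusters (2 <= k <= number of voxels).
#' @param seed Integer seed for the k-means restarts.
#' @param coords Seed coordinates (0-based x, y, z), one row per voxel.
#' @param shape Voxel grid extent.
#' @param n_restarts k-means restarts (default 100).
#' @return A [parcellation()].
#' @export
spectral_cluster <- function(w, k, seed, coords, shape, n_restarts = 100) {
  n <- nrow(w)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of seed voxels", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-8 || min(w) < 0) {
    stop("affinity matrix must be symmetric and non-negative", call. = FALSE)
  }
  labels <- spectral_labels(w, k, seed, n_restarts)
  canonicalize_labels(parcellation(labels, coords, shape, k = k))
}

spectral_labels <- function(w, k, seed, n_restarts = 100) {
  n <- nrow(w)
  d <- rowSums(w)
  d[d <= 0] <- 1e-12
  dinv <- 1 / sqrt(d)
  l <- w * (dinv %o% dinv)
  es <- eigen(l, symmetric = TRUE)
  v <- es$vectors[, seq_len(k), drop = FALSE]
  # canonical sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(v[, j]))
    if (v[i0, j] < 0) v[, j] <- -v[, j]
  }
  rn <- sqrt(rowSums(v^2))
  nz <- rn > 0
  v[nz, ] <- v[nz, , drop = FALSE] / rn[nz]
  for (attempt in 0:9) {
    fit <- with_seed(
      derive_seed(seed, attempt),
      kmeans_restarts(v, k, n_restarts)
    )
    if (!is.null(fit)) {
      return(as.integer(fit$cluster))
    }
  }
  stop("k-means produced an empty cluster in every restart", call. = FALSE)
}

#' Cluster one cross-correlation matrix over a range of k
#'
#' One independent normalized-cut solution per k in `[k_min, k_max]`; the
#' per-k runs share nothing, so they can be computed concurrently with
#' identical results.
#'
#' @param cc Cross-correlation matrix (converted to an affinity with
#'   [affinity_from_correlation()]).
#' @inheritParams spectral_cluster
#' @param k_min,k_max Cluster-count range (default 2..12).
#' @param n_workers Parallel workers for the per-k runs (forked; results
#'   are independent of the worker count).
#' @return A named list of [parcellation()]s, names `"k2"`, `"k3"`, ...;
#'   class `solution_set`.
#' @export
cluster_solutions <- function(cc, coords, shape, k_min = 2, k_max = 12,
                              seed = 1L, n_restarts = 100, n_workers = 1) {
  n <- nrow(cc)
  if (!(2 <= k_min && k_min <= k_max && k_max <= n)) {
    stop("need 2 <= k_min <= k_max <= number of seed voxels", call. = FALSE)
  }
  w <- affinity_from_correlation(cc)
  ks <- k_min:k_max
  runs <- run_units(ks, function(k) {
    spectral_cluster(w, k, derive_seed(seed, k), coords, shape, n_restarts)
  }, n_workers)
  structure(stats::setNames(runs, paste0("k", ks)), class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  ks <- vapply(x, function(p) p$k, integer(1))
  cat(
    "<solution_set> k = ", min(ks), "..", max(ks), " over ",
    length(x[[1]]$labels), " seed voxels\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname tidy.parcellation
#' @export
glance.solution_set <- function(x, ...) {
  dplyr::bind_rows(lapply(unname(x), glance.parcellation))
}

# Deterministic map over independent work units, optionally forked.
# Each unit derives its own seeds, so the split cannot change results.
run_units <- function(items, fn, n_workers = 1) {
  if (n_workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(items, fn, mc.cores = n_workers, mc.set.seed = FALSE)
  } else {
    lapply(items, fn)
  }
}
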