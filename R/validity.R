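#' Overlap frequency table between two parcellations
#'
#' Entry (i, j) counts the voxels carrying label i in A and label j in B,
#' over the voxels labeled in both parcellations. Rows and columns cover
#' the distinct labels actually present on that common domain.
#'
#' @param a,b [parcellation()]s on the same voxel grid.
#' @return Object of class `overlap_table`: the count matrix with the
#'   label values as dimnames; grand total in attribute `"N"`.
#' @export
overlap_table <- function(a, b) {
  stopifnot(inherits(a, "parcellation"), inherits(b, "parcellation"))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  bl <- stats::setNames(b$labels, key(b$coords))
  al <- a$labels
  bl <- bl[key(a$coords)]
  keep <- !is.na(bl)
  if (!any(keep)) {
    stop("parcellations share no labeled voxels", call. = FALSE)
  }
  al <- al[keep]
  bl <- bl[keep]
  t <- table(factor(al, levels = sort(unique(al))),
             factor(bl, levels = sort(unique(bl))))
  out <- matrix(as.numeric(t), nrow(t), ncol(t),
    dimnames = list(rownames(t), colnames(t))
  )
  structure(out, N = sum(out), class = c("overlap_table", "matrix"))
}

#' Cramer's V between two parcellations
#'
#' Association strength V = sqrt(chi^2 / (N * min(m - 1, n - 1))) of the
#' overlap table, where chi^2 is the usual statistic over cells with
#' nonzero expected count. 1 indicates a perfect match.
#'
#' @param t An [overlap_table()].
#' @return Score in \[0, 1\].
#' @export
cramers_v <- function(t) {
  stopifnot(inherits(t, "overlap_table"))
  m <- nrow(t)
  n <- ncol(t)
  if (m == 1 || n == 1) {
    if (m == 1 && n == 1) {
      return(1)
    }
    stop("Cramer's V undefined when exactly one parcellation is single-cluster",
      call. = FALSE
    )
  }
  big_n <- attr(t, "N")
  rs <- rowSums(t)
  cs <- colSums(t)
  expected <- outer(rs, cs) / big_n
  keep <- expected > 0
  chi2 <- sum((t[keep] - expected[keep])^2 / expected[keep])
  v2 <- chi2 / (big_n * min(m - 1, n - 1))
  sqrt(max(0, min(1, v2)))
}

#' Dice coefficient between two parcellations with corresponding labels
#'
#' Mean over clusters of 2 |A_i intersect B_i| / (|A_i| + |B_i|), on the
#' voxels labeled in both parcellations. Labels are taken as already
#' matched (run the group-labeling stage or [match_labels()] first).
#' A cluster empty in both contributes 1; empty in exactly one, 0.
#'
#' @param a,b [parcellation()]s with the same k.
#' @return Score in \[0, 1\]; 1 for identical parcellations.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "parcellation"), inherits(b, "parcellation"))
  if (a$k != b$k) stop("Dice requires the same k", call. = FALSE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  bl <- stats::setNames(b$labels, key(b$coords))
  bl <- bl[key(a$coords)]
  keep <- !is.na(bl)
  if (!any(keep)) stop("parcellations share no labeled voxels", call. = FALSE)
  al <- a$labels[keep]
  bl <- bl[keep]
  vals <- vapply(seq_len(a$k), function(c) {
    na <- sum(al == c)
    nb <- sum(bl == c)
    if (na + nb == 0) {
      return(1)
    }
    2 * sum(al == c & bl == c) / (na + nb)
  }, numeric(1))
  mean(vals)
}

#' Entropies and mutual information of an overlap table
#'
#' Plug-in estimates from the table margins and cells, in natural-log
#' units, with 0 log 0 taken as 0.
#'
#' @param t An [overlap_table()].
#' @return A one-row tibble with `h_a`, `h_b`, `mi`.
#' @export
information_summary <- function(t) {
  stopifnot(inherits(t, "overlap_table"))
  big_n <- attr(t, "N")
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  pa <- rowSums(t) / big_n
  pb <- colSums(t) / big_n
  h_a <- -sum(plogp(pa))
  h_b <- -sum(plogp(pb))
  pij <- t / big_n
  eij <- outer(pa, pb)
  mi <- sum(ifelse(pij > 0, pij * log(pij / eij), 0))
  tibble::tibble(h_a = h_a, h_b = h_b, mi = max(0, mi))
}

#' Normalized mutual information of an overlap table
#'
#' 2 I(A;B) / (H(A) + H(B)); the average-entropy normalization gives a
#' tight upper bound on the mutual information. Two single-cluster
#' parcellations (zero entropy on both sides) score 1 by convention.
#'
#' @param t An [overlap_table()].
#' @return Score in \[0, 1\].
#' @export
nmi <- function(t) {
  s <- information_summary(t)
  if (s$h_a + s$h_b == 0) {
    return(1)
  }
  min(1, 2 * s$mi / (s$h_a + s$h_b))
}

#' Variation of information of an overlap table
#'
#' VI = H(A) + H(B) - 2 I(A;B), in nats. 0 for identical partitions; the
#' upper limit is H(A) + H(B), not 1.
#'
#' @param t An [overlap_table()].
#' @return Score >= 0.
#' @export
vi <- function(t) {
  s <- information_summary(t)
  max(0, s$h_a + s$h_b - 2 * s$mi)
}

# Cosine distance matrix between rows; any pair involving an all-zero row
# has distance 1 by convention.
cosine_distance_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  d <- matrix(1, nrow(m), nrow(m))
  nz <- nrm > 0
  if (any(nz)) {
    u <- m[nz, , drop = FALSE] / nrm[nz]
    s <- tcrossprod(u)
    s <- pmin(pmax(s, -1), 1)
    d[nz, nz] <- 1 - s
  }
  diag(d) <- 0
  d
}

#' Silhouette breakdown of a parcellation
#'
#' Per-voxel silhouette S_i = (b_i - a_i) / max(a_i, b_i) under the cosine
#' distance between rows of the native connectivity matrix: a_i is the
#' mean distance to the other voxels of the voxel's own cluster, b_i the
#' smallest mean distance to any other cluster. Voxels in singleton
#' clusters get S_i = 0 by convention.
#'
#' @param native Native connectivity matrix, rows in seed order.
#' @param p [parcellation()] over the same seed order.
#' @return Tibble with columns `voxel`, `cluster`, `a`, `b`, `s`; the
#'   solution-level score is `mean(out$s)`.
#' @export
silhouette_profile <- function(native, p) {
  stopifnot(inherits(p, "parcellation"))
  if (p$k < 2) stop("silhouette requires k >= 2", call. = FALSE)
  if (nrow(native) != length(p$labels)) {
    stop("native matrix rows must match the parcellation voxels", call. = FALSE)
  }
  d <- cosine_distance_rows(native)
  n <- nrow(d)
  lab <- p$labels
  a <- numeric(n)
  b <- numeric(n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    own <- own[own != i]
    if (length(own) == 0) {
      a[i] <- 0
      b[i] <- 0
      s[i] <- 0
      next
    }
    a[i] <- mean(d[i, own])
    others <- setdiff(unique(lab), lab[i])
    b[i] <- min(vapply(others, function(c) mean(d[i, lab == c]), numeric(1)))
    denom <- max(a[i], b[i])
    s[i] <- if (denom > 0) (b[i] - a[i]) / denom else 0
  }
  tibble::tibble(voxel = seq_len(n), cluster = lab, a = a, b = b, s = s)
}

# Connected components of a voxel set under 6/18/26-connectivity; returns
# component sizes. Uses the graph of neighbor pairs.
component_sizes <- function(coords, connectivity) {
  n <- nrow(coords)
  if (n == 1) {
    return(1L)
  }
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  id <- stats::setNames(seq_len(n), key(coords))
  offsets <- neighbor_offsets(connectivity)
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[r, ], `+`)
    hit <- id[key(nb)]
    ok <- !is.na(hit)
    from <- c(from, which(ok))
    to <- c(to, hit[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$csize
}

#' Continuity index of a parcellation
#'
#' Per cluster, the size of the largest connected component divided by the
#' cluster size, averaged over clusters; 1 means every cluster is a single
#' spatial continuum without discrete voxels. Computed under 6-, 18-, or
#' 26-connectivity.
#'
#' @param p A [parcellation()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Score in (0, 1\].
#' @export
continuity_index <- function(p, connectivity = 26) {
  stopifnot(inherits(p, "parcellation"))
  vals <- vapply(seq_len(p$k), function(c) {
    sel <- p$labels == c
    if (!any(sel)) {
      return(NA_real_)
    }
    cs <- component_sizes(p$coords[sel, , drop = FALSE], connectivity)
    max(cs) / sum(sel)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Hierarchy index between a k and a k-1 solution
#'
#' With x_ij the number of voxels of cluster i (k solution) stemming from
#' cluster j (k-1 solution), the index averages max_j(x_ij) / sum_j(x_ij)
#' over the k clusters: the mean probability that a cluster has a single
#' parent. 1 indicates a perfect hierarchy (strict refinement).
#'
#' @param pk [parcellation()] with k clusters.
#' @param pkm1 [parcellation()] with k - 1 clusters, same voxel domain.
#' @return Score in (0, 1\].
#' @export
hierarchy_index <- function(pk, pkm1) {
  stopifnot(inherits(pk, "parcellation"), inherits(pkm1, "parcellation"))
  if (pkm1$k != pk$k - 1) {
    stop("second parcellation must have k - 1 clusters", call. = FALSE)
  }
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  parent <- stats::setNames(pkm1$labels, key(pkm1$coords))
  parent <- parent[key(pk$coords)]
  keep <- !is.na(parent)
  if (!any(keep)) stop("parcellations share no labeled voxels", call. = FALSE)
  x <- table(
    factor(pk$labels[keep], levels = seq_len(pk$k)),
    factor(parent[keep], levels = seq_len(pkm1$k))
  )
  x <- matrix(as.numeric(x), pk$k, pkm1$k)
  rs <- rowSums(x)
  ok <- rs > 0
  mean(apply(x[ok, , drop = FALSE], 1, max) / rs[ok])
}

#' Region contact matrix of a parcellation
#'
#' Entry (i, j), i != j, counts the voxels of region i that touch (share a
#' 26-neighborhood with) at least one voxel of region j; the diagonal is
#' excluded. A row-normalized copy (rows summing to 1, all-zero rows kept
#' zero) encodes each region's topological arrangement.
#'
#' @param p A [parcellation()].
#' @return List with `counts` and `normalized` k x k matrices, class
#'   `contact_matrix`.
#' @export
contact_matrix <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  k <- p$k
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lab <- stats::setNames(p$labels, key(p$coords))
  offsets <- neighbor_offsets(26)
  counts <- matrix(0, k, k)
  touched <- array(FALSE, c(nrow(p$coords), k))
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(p$coords, 2, offsets[r, ], `+`)
    hit <- lab[key(nb)]
    ok <- !is.na(hit) & hit != p$labels
    if (any(ok)) {
      touched[cbind(which(ok), hit[ok])] <- TRUE
    }
  }
  for (i in seq_len(k)) {
    sel <- p$labels == i
    for (j in seq_len(k)) {
      if (i != j) counts[i, j] <- sum(touched[sel, j])
    }
  }
  rs <- rowSums(counts)
  normalized <- counts
  nz <- rs > 0
  normalized[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  structure(
    list(counts = counts, normalized = normalized),
    class = "contact_matrix"
  )
}

#' Topological distance between two parcellations
#'
#' Cosine distance between the vectorized row-normalized contact matrices
#' of the two parcellations (labels harmonized beforehand, e.g. with
#' [harmonize_hemispheres()]). 0 means identical topological arrangement
#' of the subregions; an all-zero contact pattern on either side gives 1
#' by convention.
#'
#' @param left,right [parcellation()]s with the same k.
#' @return Score in \[0, 1\].
#' @export
topological_distance <- function(left, right) {
  if (left$k != right$k) {
    stop("topological distance requires the same k", call. = FALSE)
  }
  u <- as.vector(contact_matrix(left)$normalized)
  v <- as.vector(contact_matrix(right)$normalized)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(1)
  }
  max(0, min(1, 1 - sum(u * v) / (nu * nv)))
}

#' All pairwise comparison indices between two parcellations
#'
#' Convenience wrapper computing Cramer's V, Dice, NMI and VI between two
#' parcellations, optionally matching the labels of `b` to `a` first
#' (Dice presumes corresponding labels; the information indices do not
#' care).
#'
#' @param a,b [parcellation()]s with the same k.
#' @param align Match b's labels to a's by optimal assignment first.
#' @return Tibble with columns `index` (`"cv"`, `"dice"`, `"nmi"`, `"vi"`)
#'   and `value`.
#' @export
compare_parcellations <- function(a, b, align = TRUE) {
  if (align) {
    b <- apply_permutation(b, match_labels(a, b))
  }
  t <- overlap_table(a, b)
  tibble::tibble(
    index = c("cv", "dice", "nmi", "vi"),
    value = c(
      if (nrow(t) == 1 || ncol(t) == 1) {
        if (nrow(t) == 1 && ncol(t) == 1) 1 else NA_real_
      } else {
        cramers_v(t)
      },
      dice(a, b), nmi(t), vi(t)
    )
  )
}
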