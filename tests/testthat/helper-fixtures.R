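# Fixture builders and independent brute-force oracles used across the
# suite. Oracles evaluate the printed formulas directly and never call the
# implementation they check.

# Parcellation over a full grid from a 3D label array (0 = background).
grid_parcellation <- function(arr, k = max(arr), allow_empty = FALSE) {
  volume_parcellation(label_volume(arr), k = k, allow_empty = allow_empty)
}

# Parcellation on a w x h x d grid from a label vector in seed order
# (x fastest within the lexicographic (x, y, z) ordering used everywhere).
seedorder_parcellation <- function(labels, shape, k = max(labels)) {
  coords <- tractparc:::roi_grid_coords(shape)
  parcellation(labels, coords, shape, k = k)
}

random_parcellation <- function(shape, k, seed) {
  n <- prod(shape)
  repeat {
    labels <- sample.int(k, n, replace = TRUE)
    if (length(unique(labels)) == k) break
  }
  seedorder_parcellation(labels, shape, k)
}

# --- formula oracles -------------------------------------------------------

oracle_chi2 <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      if (e > 0) out <- out + (tab[i, j] - e)^2 / e
    }
  }
  out
}

oracle_cramers_v <- function(tab) {
  sqrt(oracle_chi2(tab) / (sum(tab) * min(nrow(tab) - 1, ncol(tab) - 1)))
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_mi <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        out <- out + tab[i, j] / n *
          log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  out
}

oracle_nmi <- function(tab) {
  ha <- oracle_entropy(rowSums(tab) / sum(tab))
  hb <- oracle_entropy(colSums(tab) / sum(tab))
  if (ha + hb == 0) 1 else 2 * oracle_mi(tab) / (ha + hb)
}

oracle_vi <- function(tab) {
  oracle_entropy(rowSums(tab) / sum(tab)) +
    oracle_entropy(colSums(tab) / sum(tab)) - 2 * oracle_mi(tab)
}

oracle_dice <- function(la, lb, k) {
  mean(vapply(seq_len(k), function(c) {
    na <- sum(la == c)
    nb <- sum(lb == c)
    if (na + nb == 0) 1 else 2 * sum(la == c & lb == c) / (na + nb)
  }, numeric(1)))
}

oracle_hi <- function(lk, lkm1, k) {
  vals <- vapply(seq_len(k), function(i) {
    xs <- vapply(
      seq_len(k - 1),
      function(j) sum(lk == i & lkm1 == j), numeric(1)
    )
    max(xs) / sum(xs)
  }, numeric(1))
  mean(vals)
}

# Per-voxel silhouette from an explicit distance matrix.
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      return(0)
    }
    a <- mean(d[i, own])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(c) mean(d[i, labels == c]), numeric(1)
    ))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

oracle_cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(1)
  }
  1 - sum(x * y) / (nx * ny)
}

# Normalized-cut objective of a partition: sum over clusters of
# cut(A, complement) / assoc(A, V).
ncut_objective <- function(w, labels) {
  out <- 0
  for (c in unique(labels)) {
    inside <- labels == c
    assoc <- sum(w[inside, , drop = FALSE])
    if (assoc == 0) {
      return(Inf)
    }
    cut <- sum(w[inside, !inside, drop = FALSE])
    out <- out + cut / assoc
  }
  out
}

# Exhaustive minimum of the ncut objective over all 2-way partitions.
ncut_bruteforce_min <- function(w) {
  n <- nrow(w)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    labels <- c(1L, as.integer(intToBits(code)[1:(n - 1)]) + 1L)
    if (length(unique(labels)) < 2) next
    best <- min(best, ncut_objective(w, labels))
  }
  best
}

# All permutations of 1..k (k small).
all_permutations <- function(k) {
  if (k == 1) {
    return(list(1L))
  }
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# Small blocky cohort for group/pipeline tests (cheaper than defaults).
small_phantom <- function(seed = 5, n_subjects = 6, noise = 0.1, jitter = 0) {
  phantom_spec(
    roi_shape = c(4, 4, 6), k_true = 3, n_subjects = n_subjects,
    target_shape = c(10, 10, 10), noise_mix = noise, jitter = jitter,
    master_seed = seed
  )
}

cohort_natives <- function(cohort, block_mm = 4) {
  spec <- cohort$spec
  lapply(cohort$profiles, function(pr) {
    build_native_matrix(
      pr, cohort$coords, spec$target_shape, spec$voxel_size,
      block_mm = block_mm
    )
  })
}
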