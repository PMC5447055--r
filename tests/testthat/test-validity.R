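two_parcellations <- function(la, lb, shape = c(length(la), 1, 1)) {
  list(
    a = seedorder_parcellation(la, shape),
    b = seedorder_parcellation(lb, shape)
  )
}

test_that("overlap tables count label co-occurrences on the common domain", {
  p <- two_parcellations(rep(c(1, 2), c(6, 4)), rep(c(1, 2), c(6, 4)))
  t <- overlap_table(p$a, p$b)
  expect_equal(unclass(t)[, ], diag(c(6, 4)), ignore_attr = TRUE)
  expect_equal(attr(t, "N"), 10)

  # disjoint supports: no common voxels
  arr1 <- array(0L, c(4, 1, 1))
  arr1[1:2] <- 1L
  arr2 <- array(0L, c(4, 1, 1))
  arr2[3:4] <- 1L
  expect_error(
    overlap_table(grid_parcellation(arr1), grid_parcellation(arr2)),
    "share no"
  )

  # random toy pair against a hand count
  set.seed(9)
  la <- sample(1:3, 30, replace = TRUE)
  lb <- sample(1:2, 30, replace = TRUE)
  p <- two_parcellations(la, lb)
  t <- overlap_table(p$a, p$b)
  for (i in 1:3) {
    for (j in 1:2) {
      expect_equal(t[i, j], sum(la == i & lb == j))
    }
  }
})

test_that("Cramer's V matches its formula, with exact 1 and 0 anchors", {
  p <- two_parcellations(rep(1:3, c(20, 25, 15)), rep(1:3, c(20, 25, 15)))
  expect_equal(cramers_v(overlap_table(p$a, p$b)), 1)

  # proportional (independent) table: chi-squared 0
  ind <- structure(matrix(c(4, 4, 4, 4), 2, 2),
    N = 16, class = c("overlap_table", "matrix")
  )
  expect_equal(cramers_v(ind), 0)

  mixed <- structure(matrix(c(8, 2, 2, 8), 2, 2),
    N = 20, class = c("overlap_table", "matrix")
  )
  expect_equal(cramers_v(mixed), oracle_cramers_v(matrix(c(8, 2, 2, 8), 2, 2)))

  # single-cluster cases
  both <- structure(matrix(10, 1, 1), N = 10, class = c("overlap_table", "matrix"))
  expect_equal(cramers_v(both), 1)
  one <- structure(matrix(c(5, 5), 1, 2), N = 10, class = c("overlap_table", "matrix"))
  expect_error(cramers_v(one), "undefined")
})

test_that("Dice handles identity, disjoint correspondence, and hand-counted overlap", {
  p <- two_parcellations(rep(1:2, c(6, 4)), rep(1:2, c(6, 4)))
  expect_equal(dice(p$a, p$b), 1)
  # swapped labels: disjoint correspondence
  expect_equal(dice(p$a, apply_permutation(p$b, c(2, 1))), 0)
  # A = {1..6}, {7..10}; B = {1..5}, {6..10}
  q <- two_parcellations(rep(1:2, c(6, 4)), rep(1:2, c(5, 5)))
  expect_equal(dice(q$a, q$b), (10 / 11 + 8 / 9) / 2)
  expect_error(
    dice(p$a, seedorder_parcellation(rep(1:5, 2), c(10, 1, 1))),
    "same k"
  )
})

test_that("entropies and mutual information follow the plug-in formulas", {
  p <- two_parcellations(rep(1:2, c(7, 3)), rep(1:2, c(7, 3)))
  t <- overlap_table(p$a, p$b)
  s <- information_summary(t)
  expect_equal(s$mi, s$h_a)
  expect_equal(s$h_a, s$h_b)
  expect_equal(s$h_a, oracle_entropy(c(0.7, 0.3)))

  ind <- structure(matrix(c(4, 4, 4, 4), 2, 2),
    N = 16, class = c("overlap_table", "matrix")
  )
  expect_equal(information_summary(ind)$mi, 0)

  hand <- structure(matrix(c(3, 1, 1, 3), 2, 2),
    N = 8, class = c("overlap_table", "matrix")
  )
  s2 <- information_summary(hand)
  expect_equal(s2$mi, oracle_mi(matrix(c(3, 1, 1, 3), 2, 2)), tolerance = 1e-12)
})

test_that("NMI and VI hit their identity and independence anchors", {
  p <- two_parcellations(rep(1:3, c(5, 3, 2)), rep(1:3, c(5, 3, 2)))
  t <- overlap_table(p$a, p$b)
  expect_equal(nmi(t), 1)
  expect_equal(vi(t), 0)

  ind <- structure(matrix(c(4, 4, 4, 4), 2, 2),
    N = 16, class = c("overlap_table", "matrix")
  )
  expect_equal(nmi(ind), 0)
  # independent equal-margin 2x2: VI = H(A) + H(B) = 2 ln 2
  expect_equal(vi(ind), 2 * log(2))

  hand <- structure(matrix(c(3, 1, 1, 3), 2, 2),
    N = 8, class = c("overlap_table", "matrix")
  )
  expect_equal(nmi(hand), oracle_nmi(matrix(c(3, 1, 1, 3), 2, 2)), tolerance = 1e-12)
})

test_that("VI = (H_A + H_B)(1 - NMI) on random tables", {
  set.seed(15)
  for (rep in 1:20) {
    k1 <- sample(2:4, 1)
    k2 <- sample(2:4, 1)
    tab <- matrix(stats::rpois(k1 * k2, 5) + 1, k1, k2)
    t <- structure(tab, N = sum(tab), class = c("overlap_table", "matrix"))
    s <- information_summary(t)
    expect_equal(vi(t), (s$h_a + s$h_b) * (1 - nmi(t)), tolerance = 1e-12)
  }
})

test_that("CV, NMI and VI are label-permutation invariant; Dice and HI are not", {
  set.seed(19)
  a <- random_parcellation(c(24, 1, 1), 3, 1)
  b <- random_parcellation(c(24, 1, 1), 3, 2)
  bp <- apply_permutation(b, c(3, 1, 2))
  t0 <- overlap_table(a, b)
  t1 <- overlap_table(a, bp)
  expect_equal(cramers_v(t0), cramers_v(t1), tolerance = 1e-12)
  expect_equal(nmi(t0), nmi(t1), tolerance = 1e-12)
  expect_equal(vi(t0), vi(t1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dice(a, b), dice(a, bp))))

  pk <- random_parcellation(c(24, 1, 1), 3, 3)
  pkm1 <- random_parcellation(c(24, 1, 1), 2, 4)
  expect_equal(
    hierarchy_index(apply_permutation(pk, c(2, 3, 1)), pkm1),
    hierarchy_index(pk, pkm1),
    tolerance = 1e-12
  )
})

test_that("silhouette separates tight distinct clusters and zeroes singletons", {
  # two clusters of identical rows, orthogonal across clusters
  native <- rbind(
    c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0),
    c(0, 0, 1, 0), c(0, 0, 1, 0)
  )
  p <- seedorder_parcellation(c(1, 1, 1, 2, 2), c(5, 1, 1))
  sil <- silhouette_profile(native, p)
  expect_equal(mean(sil$s), 1)

  # singleton cluster voxel scores 0 by convention
  p2 <- seedorder_parcellation(c(1, 1, 1, 2, 3), c(5, 1, 1))
  sil2 <- silhouette_profile(native, p2)
  expect_equal(sil2$s[4], 0)
  expect_equal(sil2$s[5], 0)

  # 4-row toy against the brute-force per-voxel formula
  set.seed(27)
  native3 <- matrix(stats::runif(20), 4, 5)
  p3 <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  d <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i != j) d[i, j] <- oracle_cosine_distance(native3[i, ], native3[j, ])
    }
  }
  sil3 <- silhouette_profile(native3, p3)
  expect_equal(sil3$s, oracle_silhouette(d, p3$labels), tolerance = 1e-12)
  expect_true(all(sil3$s >= -1 & sil3$s <= 1))
  expect_error(silhouette_profile(native3, seedorder_parcellation(rep(1, 4), c(4, 1, 1))), "k >= 2")
})

test_that("continuity is the mean largest-component fraction per cluster", {
  # contiguous slabs: every cluster one component
  arr <- array(rep(1:3, each = 72), c(6, 6, 6))
  p <- grid_parcellation(arr)
  for (conn in c(6, 18, 26)) {
    expect_equal(continuity_index(p, conn), 1)
  }

  # a contiguous two-cluster strip has continuity 1
  arr3 <- array(0L, c(10, 2, 1))
  arr3[, 1, 1] <- 1L # 10 voxels in a line: one component
  arr3[1:5, 2, 1] <- 2L
  arr3[6:10, 2, 1] <- 2L # contiguous: still one component
  p3 <- grid_parcellation(arr3)
  expect_equal(continuity_index(p3, 6), 1)
  arr4 <- array(0L, c(11, 2, 1))
  arr4[, 1, 1] <- 2L
  arr4[1:5, 2, 1] <- 1L
  arr4[7:11, 2, 1] <- 1L # gap at x = 6: cluster 1 splits 5 + 5
  p4 <- grid_parcellation(arr4)
  expect_equal(continuity_index(p4, 6), (0.5 + 1) / 2)

  # 26-connectivity can only merge components: index never below the 6-connected one
  set.seed(33)
  for (rep in 1:5) {
    pr <- random_parcellation(c(4, 4, 4), 3, rep)
    expect_gte(continuity_index(pr, 26), continuity_index(pr, 6))
    expect_gte(continuity_index(pr, 18), continuity_index(pr, 6))
  }
})

test_that("hierarchy index is 1 for refinements and averages parent fractions", {
  # strict refinement: split one cluster of a 3-solution into two
  lk3 <- rep(1:3, c(12, 10, 8))
  lk4 <- lk3
  lk4[lk3 == 1] <- rep(c(1, 4), c(6, 6))
  pk4 <- seedorder_parcellation(lk4, c(30, 1, 1))
  pk3 <- seedorder_parcellation(lk3, c(30, 1, 1))
  expect_equal(hierarchy_index(pk4, pk3), 1)

  # one cluster drawing equally from two parents: (1 + 1 + 0.5)/3
  lk2 <- rep(1:2, c(10, 10))
  lk3b <- c(rep(1, 5), rep(3, 10), rep(2, 5))
  p3b <- seedorder_parcellation(lk3b, c(20, 1, 1))
  p2b <- seedorder_parcellation(lk2, c(20, 1, 1))
  expect_equal(hierarchy_index(p3b, p2b), (1 + 1 + 0.5) / 3)
  expect_equal(
    hierarchy_index(p3b, p2b),
    oracle_hi(lk3b, lk2, 3),
    tolerance = 1e-12
  )
  expect_error(hierarchy_index(pk4, p2b), "k - 1")
})

test_that("contact matrices count touching voxels and normalize rows", {
  # two slabs in contact across x = 2/3
  arr <- array(0L, c(4, 2, 2))
  arr[1:2, , ] <- 1L
  arr[3:4, , ] <- 2L
  cm <- contact_matrix(grid_parcellation(arr))
  expect_equal(cm$counts[1, 2], 4) # the x = 2 face of slab 1
  expect_equal(cm$counts[2, 1], 4)
  expect_equal(cm$counts[1, 1], 0)
  expect_equal(rowSums(cm$normalized), c(1, 1))

  # isolated cluster: zero row stays zero
  arr2 <- array(0L, c(7, 1, 1))
  arr2[1:2] <- 1L
  arr2[6:7] <- 2L
  cm2 <- contact_matrix(grid_parcellation(arr2))
  expect_equal(cm2$counts, matrix(0, 2, 2))
  expect_equal(cm2$normalized, matrix(0, 2, 2))

  # translation invariance
  arr3 <- array(0L, c(6, 4, 4))
  arr3[1:2, 1:2, 1:2] <- 1L
  arr3[3:4, 1:2, 1:2] <- 2L
  shifted <- array(0L, c(6, 4, 4))
  shifted[3:4, 3:4, 3:4] <- 1L
  shifted[5:6, 3:4, 3:4] <- 2L
  expect_equal(
    contact_matrix(grid_parcellation(arr3))$counts,
    contact_matrix(grid_parcellation(shifted))$counts
  )
})

test_that("topological distance is the cosine distance of contact patterns", {
  arr <- array(rep(1:3, each = 8), c(6, 2, 2))
  p <- grid_parcellation(arr)
  expect_equal(topological_distance(p, mirror_parcellation(p)), 0)

  # orthogonal contact patterns: 1 touches 2 on the left, 1 touches 3 on
  # the right; the vectorized normalized matrices are orthogonal
  a1 <- array(0L, c(9, 2, 2))
  a1[1:2, , ] <- 1L
  a1[3:4, , ] <- 2L
  a1[8:9, , ] <- 3L # isolated
  a2 <- array(0L, c(9, 2, 2))
  a2[1:2, , ] <- 1L
  a2[3:4, , ] <- 3L
  a2[8:9, , ] <- 2L # isolated
  expect_equal(
    topological_distance(grid_parcellation(a1), grid_parcellation(a2)), 1
  )
  # an all-zero contact pattern on one side gives 1 by convention
  a3 <- array(0L, c(9, 2, 2))
  a3[1, , ] <- 1L
  a3[9, , ] <- 2L # separated clusters: zero contact vector
  a4 <- array(0L, c(9, 2, 2))
  a4[1:2, , ] <- 1L
  a4[3:4, , ] <- 2L
  expect_equal(
    topological_distance(grid_parcellation(a4), grid_parcellation(a3)), 1
  )

  # independent cosine computation on a scrambled bilateral truth
  spec <- small_phantom(seed = 51, n_subjects = 1)
  bi <- simulate_bilateral_cohort(spec)
  left <- bi$left$canonical
  right <- apply_permutation(bi$right$canonical, c(2, 1, 3))
  u <- as.vector(contact_matrix(left)$normalized)
  v <- as.vector(contact_matrix(right)$normalized)
  expect_equal(
    topological_distance(left, right),
    oracle_cosine_distance(u, v),
    tolerance = 1e-12
  )
})

test_that("index ranges hold on randomized parcellation pairs", {
  set.seed(37)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    a <- random_parcellation(c(3, 3, 4), k, rep)
    b <- random_parcellation(c(3, 3, 4), k, rep + 50)
    t <- overlap_table(a, b)
    if (nrow(t) > 1 && ncol(t) > 1) {
      expect_gte(cramers_v(t), 0)
      expect_lte(cramers_v(t), 1)
    }
    expect_gte(dice(a, b), 0)
    expect_lte(dice(a, b), 1)
    expect_gte(nmi(t), 0)
    expect_lte(nmi(t), 1)
    expect_gte(vi(t), 0)
    expect_gt(continuity_index(a, 26), 0)
    expect_lte(continuity_index(a, 26), 1)
    expect_gte(topological_distance(a, b), 0)
    expect_lte(topological_distance(a, b), 1)
  }
})
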