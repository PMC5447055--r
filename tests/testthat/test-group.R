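test_that("coincidence matrix counts same-label co-occurrence fractions", {
  p <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  # identical subjects: entries exactly 0 or 1
  g <- coincidence_matrix(list(p, p, p), threshold = 0)
  expect_true(all(g %in% c(0, 1)))
  expect_equal(g[1, 2], 1)
  expect_equal(g[1, 3], 0)
  # single subject: binary
  expect_true(all(coincidence_matrix(list(p), threshold = 0) %in% c(0, 1)))
  # a pair co-labeled in 1 of 3 subjects: 1/3, zeroed at the 0.5 threshold
  q <- seedorder_parcellation(c(1, 2, 1, 2), c(4, 1, 1))
  r <- seedorder_parcellation(c(1, 2, 2, 1), c(4, 1, 1))
  g_raw <- coincidence_matrix(list(p, q, r), threshold = 0)
  expect_equal(g_raw[1, 2], 1 / 3)
  g_thr <- coincidence_matrix(list(p, q, r), threshold = 0.5)
  expect_equal(g_thr[1, 2], 0)
  # mismatched seed sets are rejected
  s <- seedorder_parcellation(c(1, 2, 1, 2, 1), c(5, 1, 1))
  expect_error(coincidence_matrix(list(p, s)), "seed set")
})

test_that("label matching recovers identities and swaps", {
  p <- seedorder_parcellation(c(1, 1, 1, 2, 2, 3), c(6, 1, 1))
  expect_equal(match_labels(p, p), 1:3)
  swapped <- apply_permutation(p, c(2, 1, 3))
  expect_equal(match_labels(p, swapped), c(2, 1, 3))
  expect_identical(
    apply_permutation(swapped, match_labels(p, swapped))$labels,
    p$labels
  )
  q <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  expect_error(match_labels(p, q), "same k")
})

test_that("matching agrees with brute force over all k! bijections", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    n <- 30
    a <- random_parcellation(c(n, 1, 1), k, seed = rep)
    b <- random_parcellation(c(n, 1, 1), k, seed = rep + 100)
    perm <- match_labels(a, b)
    score <- function(pm) sum(a$labels == pm[b$labels])
    best <- max(vapply(all_permutations(k), score, numeric(1)))
    expect_equal(score(perm), best)
  }
})

test_that("equally optimal assignments break ties lexicographically", {
  # 4 voxels, k = 2, every bijection gives the same total overlap
  a <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  b <- seedorder_parcellation(c(1, 2, 1, 2), c(4, 1, 1))
  perm <- match_labels(a, b)
  scores <- vapply(
    all_permutations(2),
    function(pm) sum(a$labels == pm[b$labels]), numeric(1)
  )
  expect_true(all(scores == scores[1])) # verified equal-optimal
  expect_equal(perm, c(1, 2)) # lexicographically smallest bijection
})

test_that("relabeling recovers planted permutations and preserves partitions", {
  spec <- small_phantom(seed = 41, n_subjects = 5, jitter = 0)
  co <- simulate_cohort(spec)
  rel <- relabel_subjects(co$canonical, co$truth)
  for (s in 1:5) {
    # recovered bijection undoes the planted permutation at zero jitter
    expect_identical(rel$parcellations[[s]]$labels, co$canonical$labels)
    expect_equal(
      rel$permutations[[s]][co$permutations[[s]]],
      seq_len(spec$k_true)
    )
    # relabeling only renames: partition unchanged
    expect_equal(ari(rel$parcellations[[s]]$labels, co$truth[[s]]$labels), 1)
  }
  # idempotence: relabeling the relabeled cohort changes nothing
  again <- relabel_subjects(co$canonical, rel$parcellations)
  expect_identical(
    lapply(again$parcellations, `[[`, "labels"),
    lapply(rel$parcellations, `[[`, "labels")
  )
})

test_that("group scheme reproduces the shared partition of identical subjects", {
  p <- seedorder_parcellation(rep(c(1, 2, 3), each = 4), c(12, 1, 1))
  g <- coincidence_matrix(list(p, p, p))
  scheme <- group_scheme(g, 3, seed = 6, p$coords, p$shape)
  expect_equal(ari(scheme$labels, p$labels), 1)
  scheme2 <- group_scheme(g, 3, seed = 6, p$coords, p$shape)
  expect_identical(scheme$labels, scheme2$labels)
})

test_that("group scheme recovers the planted truth on a phantom cohort", {
  spec <- small_phantom(seed = 43, n_subjects = 8, noise = 0.1)
  co <- simulate_cohort(spec)
  natives <- cohort_natives(co)
  parcs <- lapply(seq_len(8), function(s) {
    spectral_cluster(
      affinity_from_correlation(cross_correlation(natives[[s]])),
      spec$k_true, derive_seed(spec$master_seed, s),
      co$coords, spec$roi_shape
    )
  })
  g <- coincidence_matrix(parcs)
  scheme <- group_scheme(g, spec$k_true, seed = 1, co$coords, spec$roi_shape)
  expect_gte(ari(scheme$labels, co$canonical$labels), 0.9)
})

test_that("hemispheric harmonization aligns mirrored parcellations", {
  left <- seedorder_parcellation(c(1, 1, 2, 2, 3, 3), c(6, 1, 1))
  mirrored_copy <- mirror_parcellation(left)
  out <- harmonize_hemispheres(left, mirrored_copy)
  expect_identical(attr(out, "permutation"), 1:3)

  swapped <- apply_permutation(mirrored_copy, c(3, 2, 1))
  out2 <- harmonize_hemispheres(left, swapped)
  expect_equal(attr(out2, "permutation"), c(3, 2, 1))
  expect_identical(mirror_parcellation(out2)$labels, left$labels)

  # harmonizing a bilateral phantom cannot worsen the topological distance
  spec <- small_phantom(seed = 47, n_subjects = 2)
  bi <- simulate_bilateral_cohort(spec)
  scrambled <- apply_permutation(bi$right$truth[[1]], c(2, 3, 1))
  before <- topological_distance(bi$left$truth[[1]], scrambled)
  after <- topological_distance(
    bi$left$truth[[1]],
    harmonize_hemispheres(bi$left$truth[[1]], scrambled)
  )
  expect_lte(after, before)
})

test_that("adjusted Rand index agrees with an independent implementation", {
  set.seed(53)
  for (rep in 1:10) {
    a <- sample.int(4, 40, replace = TRUE)
    b <- sample.int(3, 40, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(ari(c(1, 1, 2), c(2, 2, 1)), 1)
})

test_that("derived RNG substreams are deterministic and stay below 2^31", {
  expect_identical(
    tractparc:::derive_seed(42L, 7),
    tractparc:::derive_seed(42L, 7)
  )
  expect_false(
    tractparc:::derive_seed(42L, 7) == tractparc:::derive_seed(42L, 8)
  )
  expect_lt(tractparc:::derive_seed(.Machine$integer.max, 1e6), 2^31)
})
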