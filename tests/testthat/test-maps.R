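test_that("probabilistic maps are subject frequencies with denominator all subjects", {
  p1 <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  p2 <- seedorder_parcellation(c(1, 2, 2, 2), c(4, 1, 1))
  p3 <- seedorder_parcellation(c(1, 1, 2, 2), c(4, 1, 1))
  # one subject: indicator volumes
  pm1 <- probability_maps(list(p1))
  expect_true(all(unlist(pm1$maps) %in% c(0, 1)))
  # voxel 2 labeled 1 by 2 of 3 subjects
  pm <- probability_maps(list(p1, p2, p3))
  expect_equal(pm$maps[[1]][2, 1, 1], 2 / 3)
  expect_equal(pm$maps[[2]][2, 1, 1], 1 / 3)
  # per-voxel sums over clusters never exceed 1, equal 1 where all label it
  total <- Reduce(`+`, pm$maps)
  expect_true(all(total <= 1 + 1e-12))
  expect_true(all(total[cbind(1:4, 1, 1)] == 1))
  expect_error(probability_maps(list()), "at least one")
})

test_that("per-voxel probability sums stay below 1 on a phantom cohort", {
  spec <- small_phantom(seed = 3, n_subjects = 5, jitter = 1)
  co <- simulate_cohort(spec)
  rel <- relabel_subjects(co$canonical, co$truth)$parcellations
  pm <- probability_maps(rel)
  expect_true(all(Reduce(`+`, pm$maps) <= 1 + 1e-12))
})

test_that("MPM takes the per-voxel argmax and equals a lone subject's parcellation", {
  p <- grid_parcellation(array(rep(1:2, each = 4), c(2, 2, 2)))
  mpm <- maximum_probability_map(probability_maps(list(p)))
  expect_identical(mpm_parcellation(mpm)$labels, p$labels)
  expect_equal(nrow(mpm$tie_broken), 0)

  p2 <- grid_parcellation(array(c(rep(1, 4), rep(2, 4)), c(2, 2, 2)))
  p3 <- grid_parcellation(array(c(rep(1, 6), rep(2, 2)), c(2, 2, 2)))
  mpm2 <- maximum_probability_map(probability_maps(list(p2, p2, p3)))
  # voxel 5: labeled 1 by one subject of three, 2 by two: argmax is 2
  expect_equal(mpm2$volume$data[1, 1, 2], 2L)
})

test_that("MPM ties are broken by the larger 26-neighborhood average", {
  # 3x3x3 grid; at the center voxel clusters 1 and 2 tie at 0.5, but
  # cluster 2 dominates the surrounding neighborhood.
  shape <- c(3, 3, 3)
  m1 <- array(0, shape)
  m2 <- array(0, shape)
  m1[2, 2, 2] <- 0.5
  m2[2, 2, 2] <- 0.5
  m2[, , 1] <- 0.6 # 9 neighbors of the center at 0.6
  m1[1, , 2] <- 0.2 # 3 neighbors at 0.2
  pm <- structure(
    list(maps = list(m1, m2), k = 2L, shape = shape, n_subjects = 10),
    class = "probability_maps"
  )
  # hand-computed: cluster 1 average = 3 * 0.2 / 26, cluster 2 = 9 * 0.6 / 26
  mpm <- maximum_probability_map(pm)
  expect_equal(mpm$volume$data[2, 2, 2], 2L)
  expect_true(any(
    mpm$tie_broken[, 1] == 1 & mpm$tie_broken[, 2] == 1 & mpm$tie_broken[, 3] == 1
  ))

  # residual tie (identical neighborhoods) goes to the smallest label
  m2b <- m1
  pmb <- structure(
    list(maps = list(m1, m2b), k = 2L, shape = shape, n_subjects = 10),
    class = "probability_maps"
  )
  expect_equal(maximum_probability_map(pmb)$volume$data[2, 2, 2], 1L)
})

test_that("all-zero probability voxels stay background", {
  shape <- c(2, 2, 2)
  m1 <- array(0, shape)
  m1[1, 1, 1] <- 0.4
  pm <- structure(
    list(maps = list(m1, array(0, shape)), k = 2L, shape = shape, n_subjects = 5),
    class = "probability_maps"
  )
  mpm <- maximum_probability_map(pm)
  expect_equal(sum(mpm$volume$data != 0), 1)
})

test_that("noise removal flips strict-minority voxels and converges", {
  # uniform block: unchanged
  arr <- array(1L, c(3, 3, 3))
  mpm <- maximum_probability_map(probability_maps(list(grid_parcellation(arr))))
  out <- remove_noise_voxels(mpm)
  expect_identical(out$volume$data, mpm$volume$data)

  # single dissenting interior voxel inside a uniform block: flipped
  arr2 <- arr
  arr2[2, 2, 2] <- 2L
  p <- grid_parcellation(arr2)
  mpm2 <- maximum_probability_map(probability_maps(list(p)))
  out2 <- remove_noise_voxels(mpm2)
  expect_equal(out2$volume$data[2, 2, 2], 1L)
  expect_true(all(out2$volume$data == 1L))

  # idempotent once converged
  out3 <- remove_noise_voxels(out2)
  expect_identical(out3$volume$data, out2$volume$data)

  # background voxels never gain labels; label count never increases
  arr4 <- array(0L, c(4, 4, 4))
  arr4[2:3, 2:3, 2:3] <- 1L
  arr4[2, 2, 2] <- 2L
  mpm4 <- maximum_probability_map(
    probability_maps(list(grid_parcellation(arr4, allow_empty = TRUE)))
  )
  out4 <- remove_noise_voxels(mpm4)
  expect_true(all(out4$volume$data[arr4 == 0] == 0))
  expect_lte(
    length(unique(out4$volume$data[out4$volume$data != 0])),
    length(unique(arr4[arr4 != 0]))
  )
})

test_that("a 3D checkerboard halts at the pass cap with the count recorded", {
  shape <- c(4, 4, 4)
  idx <- arrayInd(1:64, shape)
  lab <- 1L + (rowSums(idx) %% 2L)
  arr <- array(lab, shape)
  mpm <- maximum_probability_map(probability_maps(list(grid_parcellation(arr))))
  out <- remove_noise_voxels(mpm, max_iter = 10)
  expect_equal(attr(out, "iterations"), 10)
  expect_true(all(out$volume$data %in% 1:2))
})

test_that("map files follow the documented naming pattern", {
  p <- grid_parcellation(array(rep(1:2, each = 4), c(2, 2, 2)))
  pm <- probability_maps(list(p))
  mpm <- maximum_probability_map(pm)
  dir <- withr::local_tempdir()
  write_maps(pm, mpm, dir, roi = "prg")
  expect_true(file.exists(file.path(dir, "prg_k2_c1_pm.nii.gz")))
  expect_true(file.exists(file.path(dir, "prg_k2_c2_pm.nii.gz")))
  expect_true(file.exists(file.path(dir, "prg_k2_mpm.nii.gz")))
  back <- read_label_volume(file.path(dir, "prg_k2_mpm.nii.gz"))
  expect_identical(back$data, mpm$volume$data)
})
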