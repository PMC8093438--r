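test_that("single-voxel t-map matches hand-evaluated statistics", {
  # group 0 = (1,2,3,4), group 1 = (3,4,5,6); hand evaluation gives
  # 1.5492 without the sample-size factor and 2.1909 for the pooled t.
  st <- volume_stack(c(lapply(1:4, function(i) array(i, c(1, 1, 1))),
                       lapply(3:6, function(i) array(i, c(1, 1, 1)))),
                     rep(c(0, 1), each = 4))
  expect_equal(compute_tmap(st, fwhm_mm = 0, mode = "literal")$grid[1],
               1.5492, tolerance = 1e-4)
  expect_equal(compute_tmap(st, fwhm_mm = 0, mode = "standard")$grid[1],
               2.1909, tolerance = 1e-4)
  # standard mode cross-checked against the reference t-test implementation
  tt <- t.test(1:4, 3:6, var.equal = TRUE)
  expect_equal(compute_tmap(st, fwhm_mm = 0, mode = "standard")$grid[1],
               abs(unname(tt$statistic)), tolerance = 1e-12)
})

test_that("standard-mode t-map equals a per-voxel t-test oracle", {
  for (s in 1:5) {
    co <- tiny_cohort(n_per_group = 10, seed = s)
    tm <- compute_tmap(co$stack, fwhm_mm = 0, mode = "standard")
    expect_lt(max(abs(as.vector(tm$grid) - oracle_tmap(co$stack))), 1e-6)
  }
})

test_that("literal mode equals direct evaluation of the printed formula", {
  co <- tiny_cohort(n_per_group = 6, seed = 11)
  tm <- compute_tmap(co$stack, fwhm_mm = 0, mode = "literal")
  X <- sapply(co$stack$volumes, as.vector)
  g0 <- co$stack$labels == 0L
  direct <- abs(rowMeans(X[, g0]) - rowMeans(X[, !g0])) /
    sqrt(0.5 * (apply(X[, g0], 1, var) + apply(X[, !g0], 1, var)))
  expect_equal(as.vector(tm$grid), direct, tolerance = 1e-12)
})

test_that("t-map is invariant to label swap, shifts, and positive scaling", {
  co <- tiny_cohort(n_per_group = 5, shift = 1, seed = 2)
  st <- co$stack
  base <- compute_tmap(st, fwhm_mm = 0)$grid
  swapped <- volume_stack(st$volumes, 1L - st$labels)
  expect_equal(compute_tmap(swapped, fwhm_mm = 0)$grid, base,
               tolerance = 1e-12)
  shifted <- volume_stack(lapply(st$volumes, `+`, 7), st$labels)
  expect_equal(compute_tmap(shifted, fwhm_mm = 0)$grid, base,
               tolerance = 1e-8)
  scaled <- volume_stack(lapply(st$volumes, `*`, 2.3), st$labels)
  expect_equal(compute_tmap(scaled, fwhm_mm = 0)$grid, base,
               tolerance = 1e-8)
})

test_that("identical groups and zero-variance voxels give t = 0", {
  set.seed(3)
  vols <- lapply(1:2, function(i) array(rnorm(4^3), c(4, 4, 4)))
  st <- volume_stack(c(vols, vols), c(0, 0, 1, 1))
  expect_true(all(compute_tmap(st, fwhm_mm = 0)$grid == 0))

  konst <- lapply(1:4, function(i) array(5, c(4, 4, 4)))
  st2 <- volume_stack(konst, c(0, 0, 1, 1))
  expect_true(all(compute_tmap(st2, fwhm_mm = 0)$grid == 0))
})

test_that("t-map never sees validation/test labels (leakage contract)", {
  co <- tiny_cohort(n_per_group = 10, shift = 1, seed = 4)
  split <- split_dataset(co$stack$labels, seed = 9)
  tr <- stack_subset(co$stack, split$subset == "train")
  m1 <- threshold_mask(compute_tmap(tr, co$brain, fwhm_mm = 0), 2)
  # permute all non-training labels; the mask must be bit-identical
  lab2 <- co$stack$labels
  hold <- which(split$subset != "train")
  lab2[hold] <- rev(lab2[hold])
  tr2 <- stack_subset(volume_stack(co$stack$volumes, lab2),
                      split$subset == "train")
  m2 <- threshold_mask(compute_tmap(tr2, co$brain, fwhm_mm = 0), 2)
  expect_identical(m1$grid, m2$grid)
})

test_that("degenerate group structure is rejected", {
  vols <- lapply(1:4, function(i) array(rnorm(3^3), c(3, 3, 3)))
  expect_error(compute_tmap(volume_stack(vols, rep(0, 4)), fwhm_mm = 0),
               class = "tmasking_onegroup_error")
  expect_error(compute_tmap(volume_stack(vols, c(0, 1, 1, 1)), fwhm_mm = 0),
               class = "tmasking_samples_error")
})

test_that("thresholding is strict and respects the support", {
  g <- array(0, c(3, 1, 1)); g[, 1, 1] <- c(0.5, 3.7, 4.1)
  sup <- array(1L, c(3, 1, 1))
  tm <- fake_tmap(g, sup)
  expect_equal(as.vector(threshold_mask(tm, 3.6)$grid), c(0, 1, 1))
  expect_equal(sum(threshold_mask(tm, 99)$grid), 0)
  # threshold 0 selects the whole support wherever t > 0
  expect_equal(as.vector(threshold_mask(tm, 0)$grid), c(1, 1, 1))
})

test_that("masks nest with threshold and selection rate is non-increasing", {
  co <- tiny_cohort(n_per_group = 8, shift = 1.5, seed = 5)
  tm <- compute_tmap(co$stack, co$brain, fwhm_mm = 0)
  prev <- NULL
  rates <- numeric(0)
  for (th in threshold_grid()) {
    m <- threshold_mask(tm, th)
    if (!is.null(prev))
      expect_true(all(m$grid <= prev))   # subset of the looser mask
    prev <- m$grid
    rates <- c(rates, selection_rate(m, co$brain))
  }
  expect_true(all(diff(rates) <= 0))
})

test_that("apply_mask is an elementwise product preserving metadata", {
  co <- tiny_cohort(n_per_group = 3, seed = 6)
  full <- binary_mask(array(1L, c(8, 8, 8)))
  expect_equal(apply_mask(co$stack, full)$volumes, co$stack$volumes)
  empty <- binary_mask(array(0L, c(8, 8, 8)))
  masked0 <- apply_mask(co$stack, empty)
  expect_true(all(vapply(masked0$volumes, function(v) all(v == 0), logical(1))))
  k <- co$region
  masked <- apply_mask(co$stack, k)
  expect_true(all(vapply(masked$volumes,
                         function(v) sum(v != 0) <= mask_size(k), logical(1))))
  expect_identical(masked$labels, co$stack$labels)
  expect_identical(masked$subject_ids, co$stack$subject_ids)
  expect_error(apply_mask(co$stack, binary_mask(array(1L, c(4, 4, 4)))),
               class = "tmasking_grid_error")
})

test_that("selection_rate counts active fractions", {
  brain <- binary_mask(array(1L, c(5, 5, 4)))
  expect_equal(selection_rate(brain, brain), 1)
  g <- array(0L, c(5, 5, 4)); g[1:10] <- 1L
  expect_equal(selection_rate(binary_mask(g), brain), 0.1)
  expect_equal(selection_rate(binary_mask(g * 0L), brain), 0)
  expect_error(selection_rate(brain, binary_mask(array(0L, c(5, 5, 4)))),
               class = "tmasking_mask_error")
})
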