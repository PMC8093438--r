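test_that("stratified splits have the reference arithmetic and balance", {
  sp <- split_dataset(rep(c(0, 1), each = 90), seed = 1)
  tab <- table(sp$subset)
  expect_equal(as.vector(tab), c(108, 36, 36))
  by_class <- table(sp$subset, sp$label)
  expect_equal(as.vector(by_class), c(54, 18, 18, 54, 18, 18))

  sp2 <- split_dataset(rep(c(0, 1), each = 5), seed = 2)
  expect_equal(as.vector(table(sp2$subset)), c(6, 2, 2))

  expect_identical(split_dataset(rep(c(0, 1), 20), seed = 7),
                   split_dataset(rep(c(0, 1), 20), seed = 7))
  expect_error(split_dataset(rep(c(0, 1), each = 7)),
               class = "tmasking_split_error")
})

test_that("the default threshold grid spans [0, 8] in 21 even steps", {
  g <- threshold_grid()
  expect_length(g, 21L)
  expect_equal(g[1], 0)
  expect_equal(g[21], 8)
  expect_lt(max(abs(diff(g) - 0.4)), 1e-12)
  expect_equal(threshold_grid(0, 1, 2), c(0, 1))
  expect_error(threshold_grid(3, 2), class = "tmasking_param_error")
})

test_that("evaluate matches a brute-force pair-counting AUC oracle", {
  ev <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)

  ev2 <- evaluate(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(ev2$auc, 0.5)

  # printed example: 4 positive-negative pairs, 3 wins -> 0.75
  ev3 <- evaluate(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ev3$auc, 0.75)

  # random scores vs enumeration of all pairs (ties counted one half)
  withr::with_seed(3, {
    p <- round(runif(40), 2)           # rounding forces some ties
    y <- rep(c(0, 1), each = 20)
  })
  pairs <- outer(p[y == 1], p[y == 0], function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(evaluate(p, y)$auc, mean(pairs))
  skip_if_not_installed("pROC")
  expect_equal(evaluate(p, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("AUC requires both classes", {
  expect_error(evaluate(c(0.2, 0.8), c(1, 1)),
               class = "tmasking_onegroup_error")
})

test_that("PE is the accuracy difference in percentage points", {
  expect_equal(performance_enhancement(75, 69), 6)
  expect_equal(performance_enhancement(75, 68), 7)
  expect_equal(performance_enhancement(50, 50), 0)
  expect_lt(performance_enhancement(60, 70), 0)
})

test_that("Dice follows its formula with the empty-mask convention", {
  d <- c(10, 10, 2)
  a <- binary_mask(array(rep(c(1L, 0L), each = 100), d))
  expect_equal(dice(a, a), 1)
  b <- binary_mask(array(rep(c(0L, 1L), each = 100), d))
  expect_equal(dice(a, b), 0)
  g1 <- array(0L, d); g1[1:100] <- 1L
  g2 <- array(0L, d); g2[51:150] <- 1L  # |A|=|B|=100, overlap 50
  expect_equal(dice(binary_mask(g1), binary_mask(g2)), 0.5)
  empty <- binary_mask(array(0L, d))
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, binary_mask(array(0L, c(5, 5, 4)))),
               class = "tmasking_grid_error")
})

make_curve <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- c("tmask_curve", class(out))
  attr(out, "grid_var") <- "threshold"
  out
}

test_that("average cross-validation is the permutation mean with its sdm", {
  base <- tidyr::expand_grid(configuration = "fs_cnn",
                             permutation = 1:2, grid = c(0, 4))
  base$seed <- base$permutation
  base$degenerate <- FALSE
  base$selection_rate <- 1
  base$train_acc <- 0.9
  base$val_acc <- 0.8
  base$val_auc <- 0.85
  base$test_auc <- 0.8
  base$test_acc <- ifelse(base$permutation == 1, 0.7, 0.8)
  agg <- aggregate_average_cv(make_curve(base))
  expect_equal(agg$test_acc_mean, c(0.75, 0.75))
  expect_equal(agg$test_acc_sdm,
               rep(sd(c(0.7, 0.8)) / sqrt(2), 2))
  # identical metrics across permutations -> spread 0
  base2 <- base; base2$test_acc <- 0.7
  expect_equal(aggregate_average_cv(make_curve(base2))$test_acc_sdm, c(0, 0))
  # permutation order is irrelevant
  shuf <- make_curve(base[sample(nrow(base)), ])
  expect_equal(aggregate_average_cv(shuf), agg)
})

test_that("classical cross-validation selects on validation only", {
  df <- tidyr::expand_grid(configuration = "fs_cnn", permutation = 1:3,
                           grid = c(0, 2, 4))
  df$seed <- df$permutation
  df$degenerate <- FALSE
  df$selection_rate <- 1
  df$train_acc <- 1
  df$val_acc <- c(0.5, 0.6, 0.7,  0.9, 0.8, 0.7,  0.6, 0.6, 0.6)
  df$val_auc <- 0.5
  df$test_acc <- runif(9)
  df$test_auc <- runif(9)
  pick <- aggregate_classical_cv(make_curve(df))
  expect_equal(pick$permutation, 2L)   # val_acc 0.9 dominates
  expect_equal(pick$grid, 0)
  # test-set relabeling never changes the selection (leakage check)
  df2 <- df
  df2$test_acc <- rev(df2$test_acc)
  df2$test_auc <- rev(df2$test_auc)
  pick2 <- aggregate_classical_cv(make_curve(df2))
  expect_equal(pick2[c("permutation", "grid")], pick[c("permutation", "grid")])
  # ties on val_acc break by val_auc, then by lower grid value
  df$val_acc <- 0.7
  df$val_auc <- c(0.6, 0.9, 0.6,  0.6, 0.6, 0.9,  0.6, 0.6, 0.9)
  pick3 <- aggregate_classical_cv(make_curve(df))
  expect_equal(pick3$grid, 2)          # val_auc 0.9 first at grid 2, perm 1
  expect_equal(pick3$permutation, 1L)
})

test_that("run_configuration sweeps, flags degenerate points, and nests rates", {
  co <- tiny_cohort(n_per_group = 10, shift = 2, seed = 61)
  cohort <- list(stack = co$stack, brain_mask = co$brain)
  curve <- run_configuration("fs_linear", cohort, grid = c(0, 2, 99),
                             n_permutations = 2, seed = 3, fwhm_mm = 0)
  expect_s3_class(curve, "tmask_curve")
  expect_equal(nrow(curve), 6L)
  expect_true(all(curve$degenerate[curve$grid == 99]))
  expect_equal(curve$test_acc[curve$grid == 99], c(0.5, 0.5))
  for (p in 1:2) {
    r <- curve$selection_rate[curve$permutation == p]
    expect_true(all(diff(r) <= 0))
  }
  expect_true(all(curve$val_auc >= 0 & curve$val_auc <= 1))
  # tidy/glance interfaces
  long <- tidy(curve)
  expect_true(all(c("metric", "value") %in% names(long)))
  expect_equal(nrow(long), 6L * 6L)
  gl <- glance(curve)
  expect_equal(nrow(gl), 1L)
  # raw and norm collapse to a single whole-brain point per permutation
  raw <- run_configuration("raw", cohort, n_permutations = 2, seed = 3,
                           fwhm_mm = 0)
  expect_equal(nrow(raw), 2L)
  expect_equal(raw$selection_rate, c(1, 1))
})

test_that("a Bernoulli knockout with p = 0 reproduces fs_cnn exactly", {
  co <- tiny_cohort(n_per_group = 5, shift = 2, seed = 71)
  cohort <- list(stack = co$stack, brain_mask = co$brain)
  mc <- cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                   trunk_blocks = list(trunk_block("separable", 4,
                                                   pool = TRUE)),
                   fc_sizes = c(8, 4))
  sch <- training_schedule(max_epochs = 3)
  a <- run_configuration("fs_cnn", cohort, grid = 2, n_permutations = 1,
                         seed = 5, model_config = mc, schedule = sch,
                         fwhm_mm = 0)
  b <- run_configuration("fs_bernoulli", cohort, grid = 2, n_permutations = 1,
                         seed = 5, model_config = mc, schedule = sch,
                         fwhm_mm = 0, bernoulli_p = 0)
  expect_equal(a$test_acc, b$test_acc)
  expect_equal(a$val_auc, b$val_auc)
  expect_equal(a$selection_rate, b$selection_rate)
})
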