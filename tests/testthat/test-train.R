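test_that("early stopping fires patience epochs after the best loss", {
  # scripted loss sequences through the stopping logic
  dec <- seq(1, 0.1, length.out = 30)
  expect_identical(early_stopping_point(dec, 10)$stop_epoch, NA_integer_)
  expect_equal(early_stopping_point(dec, 10)$best_epoch, 30L)

  flat <- c(0.9, 0.7, 0.5, rep(0.6, 12))     # minimum at epoch 3, then flat
  es <- early_stopping_point(flat, 10)
  expect_equal(es$best_epoch, 3L)
  expect_equal(es$stop_epoch, 13L)           # 3 + patience

  bumpy <- c(0.9, 0.5, 0.6, 0.4, rep(0.45, 20))
  es2 <- early_stopping_point(bumpy, 5)
  expect_equal(es2$best_epoch, 4L)
  expect_equal(es2$stop_epoch, 9L)
})

test_that("the training loop stops and restores consistently with the rule", {
  co <- tiny_cohort(n_per_group = 5, shift = 0, seed = 31)
  m <- build_cnn(cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                            trunk_blocks = list(trunk_block("separable", 4,
                                                            pool = TRUE)),
                            fc_sizes = c(8, 4)), seed = 1)
  sch <- training_schedule(max_epochs = 25, patience = 3, seed = 2)
  fit <- train_cnn(m, co$stack, co$stack, sch)
  es <- early_stopping_point(fit$history$val_loss, 3)
  expect_equal(fit$best_epoch, es$best_epoch)
  if (!is.na(es$stop_epoch))
    expect_equal(nrow(fit$history), es$stop_epoch)
})

test_that("a 6-sample separable toy cohort is memorized", {
  withr::with_seed(11, {
    vols <- lapply(rep(c(0, 1), each = 3), function(l)
      array(rnorm(8^3) + l * 1.5, c(8, 8, 8)))
  })
  st <- volume_stack(vols, rep(c(0, 1), each = 3))
  m <- build_cnn(cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                            trunk_blocks = list(trunk_block("separable", 4,
                                                            pool = TRUE)),
                            fc_sizes = c(8, 4)), seed = 3)
  sch <- training_schedule(base_lr = 0.01, decay = 1, max_epochs = 200,
                           patience = 200, seed = 4)
  fit <- train_cnn(m, st, st, sch)
  expect_equal(max(fit$history$train_acc), 1)
})

test_that("training is bit-reproducible under a fixed seed", {
  co <- tiny_cohort(n_per_group = 4, shift = 1, seed = 41)
  run <- function() {
    m <- build_cnn(cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                              trunk_blocks = list(trunk_block("separable", 4,
                                                              pool = TRUE)),
                              fc_sizes = c(8, 4)), seed = 5)
    train_cnn(m, co$stack, co$stack,
              training_schedule(max_epochs = 5, seed = 6))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(predict_proba(f1, co$stack), predict_proba(f2, co$stack))
})

test_that("single-class training sets are rejected", {
  co <- tiny_cohort(n_per_group = 3, seed = 51)
  st <- volume_stack(co$stack$volumes, rep(0L, 6))
  m <- build_cnn(cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                            trunk_blocks = list(trunk_block("separable", 4,
                                                            pool = TRUE)),
                            fc_sizes = c(8, 4)), seed = 1)
  expect_error(train_cnn(m, st, st, training_schedule(max_epochs = 2)),
               class = "tmasking_onegroup_error")
})

test_that("the mean-intensity linear baseline behaves like its Bayes rule", {
  dims <- c(6, 6, 6)
  mask <- binary_mask(array(1L, dims))
  mk <- function(means, labels) {
    volume_stack(lapply(means, function(m) array(m, dims)), labels)
  }
  # class means separated by many pooled sds -> perfect training accuracy
  tr <- mk(c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)), rep(c(0, 1), each = 5))
  fit <- linear_baseline(tr, mask)
  ev <- evaluate(predict_proba(fit, tr), tr$labels)
  expect_equal(ev$accuracy, 1)
  # uninformative constant feature -> chance on balanced data
  tr2 <- mk(rep(1, 8), rep(c(0, 1), each = 4))
  fit2 <- linear_baseline(tr2, mask)
  expect_equal(evaluate(predict_proba(fit2, tr2), tr2$labels)$accuracy, 0.5)
  # symmetric classes -> decision boundary near the midpoint of the means
  withr::with_seed(8, {
    f0 <- rnorm(60, 0, 1); f1 <- rnorm(60, 2, 1)
  })
  tr3 <- mk(c(f0, f1), rep(c(0, 1), each = 60))
  fit3 <- linear_baseline(tr3, mask)
  co <- coef(fit3$fit)
  boundary <- -co[1] / co[2]
  expect_lt(abs(boundary - 1), 0.5)
  # empty mask
  expect_error(linear_baseline(tr3, binary_mask(array(0L, dims))),
               class = "tmasking_mask_error")
})
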