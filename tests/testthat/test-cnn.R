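desk8 <- function(...) {
  args <- utils::modifyList(
    list(input_dim = c(8, 8, 8), stream_channels = c(2, 2),
         trunk_blocks = list(trunk_block("separable", 4, pool = TRUE)),
         fc_sizes = c(8, 4)),
    list(...))
  do.call(cnn_config, args)
}

test_that("a built model produces one probability in (0,1) per input", {
  m <- build_cnn(desk8(), seed = 1)
  set.seed(2)
  st <- volume_stack(lapply(1:3, function(i) array(rnorm(8^3), c(8, 8, 8))),
                     c(0, 1, 0))
  p <- predict_proba(m, st)
  expect_length(p, 3L)
  expect_true(all(p > 0 & p < 1))
})

test_that("the concatenate layer carries the sum of the stream channels", {
  m <- build_cnn(desk8(), seed = 1)
  fw <- tmasking:::cnn_forward(m, matrix(rnorm(8^3), ncol = 1), 1L)
  expect_equal(sum(fw$caches$concat$split), 2L * m$config$stream_channels[2])
  expect_equal(ncol(fw$caches$concat$x), m$config$concat_channels)
})

test_that("shared stream weights make the two streams identical", {
  m <- build_cnn(desk8(share_stream_weights = TRUE), seed = 1)
  expect_false(any(grepl("^s2\\.", names(m$params))))
  fw <- tmasking:::cnn_forward(m, matrix(rnorm(8^3), ncol = 1), 1L)
  sp <- fw$caches$concat$split
  expect_equal(fw$caches$concat$x[, seq_len(sp[1])],
               fw$caches$concat$x[, sp[1] + seq_len(sp[2])])
})

test_that("parameter count grows monotonically with widths", {
  n1 <- n_params(build_cnn(desk8(), seed = 1))
  n2 <- n_params(build_cnn(desk8(stream_channels = c(4, 4)), seed = 1))
  n3 <- n_params(build_cnn(cnn_config(
    c(8, 8, 8), stream_channels = c(4, 4),
    trunk_blocks = list(trunk_block("separable", 16, pool = TRUE)),
    fc_sizes = c(8, 4)), seed = 1))
  expect_lt(n1, n2)
  expect_lt(n2, n3)
})

test_that("incompatible shapes are rejected at configuration time", {
  expect_error(cnn_config(c(2, 2, 2)), class = "tmasking_config_error")
  expect_error(desk8(fc_sizes = c(8, 5)), class = "tmasking_config_error")
  expect_error(cnn_config(c(8, 8, 8), trunk_blocks =
                 list(trunk_block("grouped", 6, groups = 4))),
               class = "tmasking_config_error")
})

test_that("the learning-rate schedule follows the decaying exponential", {
  sch <- training_schedule()
  expect_equal(learning_rate(0, sch), 0.001)
  expect_equal(learning_rate(10, sch), 3e-4)
  expect_equal(learning_rate(20, sch), 9e-5)
  lrs <- vapply(0:30, learning_rate, numeric(1), schedule = sch)
  expect_true(all(diff(lrs) < 0))
})

test_that("backpropagation matches numeric finite differences", {
  cfg <- cnn_config(c(8, 8, 8), stream_channels = c(2, 2),
                    trunk_blocks = list(
                      trunk_block("separable", 4, pool = FALSE),
                      trunk_block("grouped", 4, pool = FALSE),
                      trunk_block("conv", 4, pool = TRUE)),
                    fc_sizes = c(8, 4), dropout_rate = 0, l2_penalty = 0)
  m <- build_cnn(cfg, seed = 3)
  set.seed(42)
  n <- 3L
  x <- matrix(rnorm(n * 8^3), ncol = 1)
  y <- c(0, 1, 1)
  lossfn <- function(mm) {
    fw <- tmasking:::cnn_forward(mm, x, n, training = TRUE)
    mean(pmax(fw$logit, 0) - fw$logit * y + log1p(exp(-abs(fw$logit))))
  }
  fw <- tmasking:::cnn_forward(m, x, n, training = TRUE)
  bw <- tmasking:::cnn_backward(m, fw, (fw$prob - y) / n)
  eps <- 1e-5
  set.seed(7)
  check_one <- function(nm, g, i) {
    m2 <- m; m3 <- m
    if (is.null(g)) {
      m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      ana <- bw$grads[[nm]][i]
    } else {
      m2$params[[nm]][[g]][i] <- m2$params[[nm]][[g]][i] + eps
      m3$params[[nm]][[g]][i] <- m3$params[[nm]][[g]][i] - eps
      ana <- bw$grads[[nm]][[g]][i]
    }
    num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
    # absolute slack covers finite-difference noise on near-zero gradients
    # (e.g. conv biases cancelled by the following batch norm)
    expect_true(abs(num - ana) < 1e-6 ||
                  abs(num - ana) / (abs(num) + abs(ana)) < 1e-4,
                label = sprintf("gradient of %s[%d]", nm, i))
  }
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    if (is.list(p)) {
      g <- sample(length(p), 1)
      for (i in sample(length(p[[g]]), 2)) check_one(nm, g, i)
    } else {
      for (i in sample(length(p), min(2, length(p)))) check_one(nm, NULL, i)
    }
  }
})

test_that("without L2 and dropout the training loss is plain cross-entropy", {
  m <- build_cnn(desk8(dropout_rate = 0, l2_penalty = 0), seed = 5)
  set.seed(6)
  x <- matrix(rnorm(2 * 8^3), ncol = 1)
  y <- c(1, 0)
  fw <- tmasking:::cnn_forward(m, x, 2L, training = TRUE)
  p <- fw$prob
  hand <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(tmasking:::bce_from_logits_(fw$logit, y) +
                 tmasking:::l2_term_(m$params, m$config$l2_penalty),
               hand, tolerance = 1e-10)
})

test_that("batch inference equals one-by-one inference", {
  m <- build_cnn(desk8(), seed = 8)
  set.seed(9)
  st <- volume_stack(lapply(1:11, function(i) array(rnorm(8^3), c(8, 8, 8))),
                     rep(c(0, 1), length.out = 11))
  p_batch <- predict_proba(m, st)
  p_single <- vapply(1:11, function(i)
    predict_proba(m, stack_subset(st, i)), numeric(1))
  expect_equal(p_batch, p_single, tolerance = 1e-5)
  # duplicated subject volume gets an identical probability
  st2 <- volume_stack(st$volumes[c(1, 1)], c(0, 0), c("a", "b"))
  expect_equal(predict_proba(m, st2)[1], predict_proba(m, st2)[2])
})

test_that("initialization is reproducible under a fixed seed", {
  m1 <- build_cnn(desk8(), seed = 21)
  m2 <- build_cnn(desk8(), seed = 21)
  expect_identical(m1$params, m2$params)
})

test_that("the paper-like preset builds on an MNI-like grid", {
  cfg <- cnn_preset("paper-like", c(91, 109, 91))
  m <- build_cnn(cfg, seed = 1)
  expect_gt(n_params(m), n_params(build_cnn(cnn_preset("desk", c(24, 24, 24)),
                                            seed = 1)))
})
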