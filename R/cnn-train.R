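#' Training schedule for the CNN
#'
#' Defaults follow the reference recipe: Adam with an exponentially
#' decaying learning rate `0.001 * 0.3^(epoch/10)` (continuous exponent by
#' default; set `stepped = TRUE` for a stair-step decay), batches of 6
#' samples drawn by random permutation until the dataset is exhausted, and
#' early stopping with patience 10 that restores the weights of the epoch
#' with minimum validation loss.
#'
#' @param base_lr Base learning rate (default 0.001).
#' @param decay Decay factor per period (default 0.3).
#' @param decay_period_epochs Decay period in epochs (default 10).
#' @param batch_size Mini-batch size (default 6).
#' @param max_epochs Maximum number of epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param stepped Use `floor(epoch/period)` in the decay exponent.
#' @param seed Optional integer seed; with a seed fixed, training is
#'   bit-reproducible (identical history and weights across runs).
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(base_lr = 0.001, decay = 0.3,
                              decay_period_epochs = 10, batch_size = 6,
                              max_epochs = 50, patience = 10,
                              stepped = FALSE, seed = NULL) {
  stopifnot(base_lr > 0, decay > 0, decay_period_epochs > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(base_lr = base_lr, decay = decay,
                 decay_period_epochs = decay_period_epochs,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 stepped = isTRUE(stepped), seed = seed),
            class = "training_schedule")
}

#' Learning rate at a given epoch
#'
#' `base_lr * decay^(epoch / decay_period_epochs)`, with epoch counted from
#' 0; strictly decreasing in epoch for decay < 1.
#'
#' @param epoch Non-negative integer epoch index (0-based).
#' @param schedule A [training_schedule()].
#' @return The learning rate.
#' @export
learning_rate <- function(epoch, schedule = training_schedule()) {
  stopifnot(epoch >= 0)
  e <- if (schedule$stepped) floor(epoch / schedule$decay_period_epochs)
       else epoch / schedule$decay_period_epochs
  schedule$base_lr * schedule$decay^e
}

#' Early-stopping decision for a validation-loss sequence
#'
#' Walks the per-epoch validation losses in order and reports the epoch
#' with minimal loss seen so far (`best_epoch`, whose weights are restored)
#' and the epoch at which training stops (`stop_epoch`): the first epoch
#' lying `patience` epochs past the running best, or `NA` if the sequence
#' ends without triggering.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Patience in epochs (>= 1).
#' @return List with `best_epoch` and `stop_epoch` (1-based).
#' @export
early_stopping_point <- function(val_losses, patience) {
  stopifnot(patience >= 1)
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) best <- e
    if (e - best >= patience)
      return(list(best_epoch = best, stop_epoch = e))
  }
  list(best_epoch = best, stop_epoch = NA_integer_)
}

# Numerically stable binary cross-entropy from logits, mean over samples.
bce_from_logits_ <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

l2_term_ <- function(params, lambda) {
  if (lambda == 0) return(0)
  w <- grep("\\.(W|Wd|Wp|Wg)$", names(params), value = TRUE)
  lambda * sum(vapply(params[w], function(p) {
    if (is.list(p)) sum(vapply(p, function(q) sum(q^2), numeric(1)))
    else sum(p^2)
  }, numeric(1)))
}

tensor_op_ <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) f(x, y), a, b) else f(a, b)
}

zeros_like_ <- function(p) {
  if (is.list(p)) lapply(p, function(q) q * 0) else p * 0
}

# Inference-mode loss/accuracy over a whole set, in small batches.
eval_set_ <- function(model, x, y, V) {
  n <- length(y)
  logit <- numeric(n)
  bs <- 8L
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    rows <- as.vector(vapply(idx, function(s) (s - 1L) * V + seq_len(V),
                             integer(V)))
    fw <- cnn_forward(model, x[rows, , drop = FALSE], length(idx),
                      training = FALSE)
    logit[idx] <- fw$logit
  }
  list(loss = bce_from_logits_(logit, y),
       acc = mean((logit > 0) == (y == 1)))
}

#' Train the 3D CNN
#'
#' Minimizes binary cross-entropy plus the configured L2 penalty with Adam,
#' under the learning-rate schedule, drawing batches by random permutation
#' each epoch until the dataset is exhausted. Per-epoch training
#' loss/accuracy are the running averages over the epoch's mini-batches;
#' validation loss/accuracy are computed in inference mode. Training stops
#' early when validation loss has not improved for `patience` epochs, and
#' the weights of the best-validation-loss epoch are restored either way.
#'
#' @param model An untrained (or warm) `tmask_cnn` from [build_cnn()].
#' @param train_stack,val_stack [volume_stack()]s of (masked) volumes;
#'   the training stack must contain both classes.
#' @param schedule A [training_schedule()].
#' @return The trained model, with `$history` a tibble of per-epoch
#'   `epoch`, `lr`, `train_loss`, `val_loss`, `train_acc`, `val_acc`, and
#'   `$best_epoch`.
#' @export
train_cnn <- function(model, train_stack, val_stack,
                      schedule = training_schedule()) {
  if (length(unique(train_stack$labels)) < 2L)
    abort("one-group error: training set must contain both classes.",
          class = "tmasking_onegroup_error")
  cfg <- model$config
  V <- as.integer(prod(cfg$input_dim))
  xtr <- stack_to_mat(train_stack); ytr <- train_stack$labels
  xva <- stack_to_mat(val_stack); yva <- val_stack$labels
  ntr <- length(ytr)
  lambda <- cfg$l2_penalty
  adam_m <- lapply(model$params, zeros_like_)
  adam_v <- lapply(model$params, zeros_like_)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0L
  hist <- vector("list", schedule$max_epochs)
  best <- list(epoch = 0L, loss = Inf, params = NULL, bn = NULL)
  with_seed_(schedule$seed, {
    for (epoch in seq_len(schedule$max_epochs)) {
      lr <- learning_rate(epoch - 1L, schedule)
      perm <- sample.int(ntr)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1L, ntr, by = schedule$batch_size)) {
        idx <- perm[start:min(start + schedule$batch_size - 1L, ntr)]
        rows <- as.vector(vapply(idx, function(s) (s - 1L) * V + seq_len(V),
                                 integer(V)))
        fw <- cnn_forward(model, xtr[rows, , drop = FALSE], length(idx),
                          training = TRUE)
        model$bn <- fw$bn
        yb <- ytr[idx]
        loss <- bce_from_logits_(fw$logit, yb) + l2_term_(model$params, lambda)
        if (!is.finite(loss))
          abort(sprintf("diverged: non-finite loss at epoch %d.", epoch),
                class = "tmasking_diverged_error")
        ep_loss <- ep_loss + loss * length(yb)
        ep_hits <- ep_hits + sum((fw$logit > 0) == (yb == 1))
        dlogit <- (fw$prob - yb) / length(yb)
        bw <- cnn_backward(model, fw, dlogit)
        G <- bw$grads
        tstep <- tstep + 1L
        for (nm in names(model$params)) {
          g <- G[[nm]]
          if (is.null(g)) next
          if (lambda > 0 && grepl("\\.(W|Wd|Wp|Wg)$", nm))
            g <- tensor_op_(g, model$params[[nm]],
                            function(gg, ww) gg + 2 * lambda * ww)
          adam_m[[nm]] <- tensor_op_(adam_m[[nm]], g,
                                     function(m, gg) b1 * m + (1 - b1) * gg)
          adam_v[[nm]] <- tensor_op_(adam_v[[nm]], g,
                                     function(v, gg) b2 * v + (1 - b2) * gg^2)
          mh <- tensor_op_(adam_m[[nm]], adam_m[[nm]],
                           function(m, .) m / (1 - b1^tstep))
          vh <- tensor_op_(adam_v[[nm]], adam_v[[nm]],
                           function(v, .) v / (1 - b2^tstep))
          model$params[[nm]] <- tensor_op_(
            model$params[[nm]], tensor_op_(mh, vh,
                                           function(m, v) m / (sqrt(v) + eps)),
            function(p, upd) p - lr * upd)
        }
      }
      va <- eval_set_(model, xva, yva, V)
      if (!is.finite(va$loss))
        abort(sprintf("diverged: non-finite loss at epoch %d.", epoch),
              class = "tmasking_diverged_error")
      hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                              train_loss = ep_loss / ntr, val_loss = va$loss,
                              train_acc = ep_hits / ntr, val_acc = va$acc)
      if (va$loss < best$loss) {
        best <- list(epoch = epoch, loss = va$loss, params = model$params,
                     bn = model$bn)
      }
      if (epoch - best$epoch >= schedule$patience) break
    }
  })
  if (!is.null(best$params)) {
    model$params <- best$params
    model$bn <- best$bn
  }
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}
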