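#' Specify a trunk block of the 3D CNN
#'
#' @param kind `"conv"` (standard), `"separable"` (depthwise + pointwise) or
#'   `"grouped"` (channel-group) 3D convolution.
#' @param channels Output channel count.
#' @param pool Whether the block ends in 2x2x2 max-pooling. Defaults to
#'   `TRUE` for standard conv blocks and `FALSE` otherwise, the usual
#'   placement when factorized blocks refine rather than downsample.
#' @param groups Number of channel groups for `"grouped"` blocks.
#' @return A block spec list.
#' @export
trunk_block <- function(kind = c("conv", "separable", "grouped"), channels,
                        pool = NULL, groups = 2L) {
  kind <- match.arg(kind)
  if (is.null(pool)) pool <- kind == "conv"
  list(kind = kind, channels = as.integer(channels), pool = pool,
       groups = as.integer(groups))
}

#' Configure the Siamese 3D CNN
#'
#' The network feeds the same masked volume into two parallel convolutional
#' streams (two conv blocks each), concatenates their activation maps along
#' the channel axis, applies a residual add-block, then a trunk of
#' standard/separable/grouped convolutional blocks, and finally two fully
#' connected blocks ending in a 4-dimensional feature vector feeding a
#' logistic output. Each convolutional block is convolution, batch
#' normalization, ELU, max-pooling (conv blocks), dropout; each FC block is
#' fully connected, batch normalization, ELU, dropout.
#'
#' @param input_dim Length-3 integer spatial input dimensions.
#' @param stream_channels Length-2 integer: output channels of the two conv
#'   blocks in each stream (both streams use the same widths).
#' @param trunk_blocks List of [trunk_block()] specs applied after the
#'   add-block.
#' @param fc_sizes Two fully connected widths; the last must be 4 (the
#'   feature vector handed to the logistic classifier).
#' @param dropout_rate Dropout probability in \[0, 1) used in every block
#'   (default 0.1).
#' @param l2_penalty L2 penalty coefficient on all convolutional and FC
#'   weights (default 5e-5); the penalty term is `l2_penalty * sum(W^2)`.
#' @param share_stream_weights If `TRUE` the two streams share one set of
#'   parameters (the strict Siamese reading); default `FALSE` (independent
#'   streams).
#' @param kernel Odd cubic kernel size (default 3).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_dim, stream_channels = c(2, 2),
                       trunk_blocks = list(trunk_block("separable", 4,
                                                       pool = TRUE)),
                       fc_sizes = c(16, 4), dropout_rate = 0.1,
                       l2_penalty = 5e-5, share_stream_weights = FALSE,
                       kernel = 3L) {
  input_dim <- as.integer(input_dim)
  stopifnot(length(input_dim) == 3L, length(stream_channels) == 2L,
            length(fc_sizes) == 2L, kernel %% 2L == 1L)
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort("`dropout_rate` must be in [0, 1).", class = "tmasking_param_error")
  if (l2_penalty < 0)
    abort("`l2_penalty` must be non-negative.", class = "tmasking_param_error")
  if (fc_sizes[2] != 4L)
    abort("configuration error: the final feature dimension must be 4.",
          class = "tmasking_config_error")
  dims <- input_dim
  for (i in 1:2) {
    if (any(dims < 2L))
      abort("configuration error: spatial dimensions collapse below 1 in the streams.",
            class = "tmasking_config_error")
    dims <- dims %/% 2L
  }
  concat_ch <- 2L * stream_channels[2]
  ch <- concat_ch
  for (blk in trunk_blocks) {
    if (blk$kind == "separable" && blk$channels %% 1L != 0)
      abort("bad trunk block", class = "tmasking_config_error")
    if (blk$kind == "grouped" &&
        (ch %% blk$groups != 0L || blk$channels %% blk$groups != 0L))
      abort("configuration error: grouped block channels must divide by groups.",
            class = "tmasking_config_error")
    ch <- blk$channels
    if (blk$pool) {
      if (any(dims < 2L))
        abort("configuration error: spatial dimensions collapse below 1 in the trunk.",
              class = "tmasking_config_error")
      dims <- dims %/% 2L
    }
  }
  structure(
    list(input_dim = input_dim, stream_channels = as.integer(stream_channels),
         trunk_blocks = trunk_blocks, fc_sizes = as.integer(fc_sizes),
         dropout_rate = dropout_rate, l2_penalty = l2_penalty,
         share_stream_weights = isTRUE(share_stream_weights),
         kernel = as.integer(kernel),
         concat_channels = concat_ch, final_dims = dims, final_channels = ch),
    class = "cnn_config")
}

#' Ready-made CNN configurations
#'
#' `"desk"` is a compact configuration for 24-48 voxel cubic phantoms,
#' trainable in seconds-to-minutes on one CPU; `"paper-like"` scales the
#' same topology up for ~MNI-grid (91x109x91) volumes. Both keep the fixed
#' macro-topology (two streams, concatenate, residual add-block,
#' separable/grouped trunk, two FC blocks, 4-dim feature, logistic output).
#'
#' @param preset `"desk"` or `"paper-like"`.
#' @param input_dim Length-3 spatial input dimensions.
#' @param ... Overrides passed on to [cnn_config()].
#' @return A [cnn_config()].
#' @export
cnn_preset <- function(preset = c("desk", "paper-like"), input_dim, ...) {
  preset <- match.arg(preset)
  args <- if (preset == "desk") {
    list(input_dim = input_dim, stream_channels = c(2, 2),
         trunk_blocks = list(trunk_block("separable", 4, pool = TRUE)),
         fc_sizes = c(16, 4))
  } else {
    list(input_dim = input_dim, stream_channels = c(8, 16),
         trunk_blocks = list(trunk_block("grouped", 32, pool = TRUE, groups = 4),
                             trunk_block("separable", 32, pool = TRUE)),
         fc_sizes = c(32, 4))
  }
  do.call(cnn_config, modifyList(args, list(...)))
}

he_init_ <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build (initialize) the Siamese 3D CNN
#'
#' Allocates He-initialized weights, zero biases and unit-gamma batch-norm
#' parameters for the topology described by the config.
#'
#' @param config A [cnn_config()].
#' @param seed Optional integer seed making initialization reproducible.
#' @return An object of class `tmask_cnn` (untrained).
#' @export
build_cnn <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cnn_config"))
  k3 <- config$kernel^3
  P <- list(); B <- list()
  add_bn <- function(nm, C) {
    P[[paste0(nm, ".gamma")]] <<- rep(1, C)
    P[[paste0(nm, ".beta")]] <<- rep(0, C)
    B[[nm]] <<- list(mean = rep(0, C), var = rep(1, C))
  }
  with_seed_(seed, {
    n_streams <- if (config$share_stream_weights) 1L else 2L
    for (s in seq_len(n_streams)) {
      cin <- 1L
      for (b in 1:2) {
        nm <- sprintf("s%d.b%d", s, b)
        cout <- config$stream_channels[b]
        P[[paste0(nm, ".W")]] <- he_init_(cin * k3, cout, cin * k3)
        P[[paste0(nm, ".b")]] <- rep(0, cout)
        add_bn(nm, cout)
        cin <- cout
      }
    }
    C <- config$concat_channels
    P[["add.W"]] <- he_init_(C * k3, C, C * k3)
    P[["add.b"]] <- rep(0, C)
    add_bn("add", C)
    cin <- C
    for (t in seq_along(config$trunk_blocks)) {
      blk <- config$trunk_blocks[[t]]
      nm <- sprintf("t%d", t)
      if (blk$kind == "conv") {
        P[[paste0(nm, ".W")]] <- he_init_(cin * k3, blk$channels, cin * k3)
      } else if (blk$kind == "separable") {
        if (blk$channels %% cin != 0L && blk$channels != cin) {
          # pointwise handles any channel change; depthwise stays per-channel
        }
        P[[paste0(nm, ".Wd")]] <- he_init_(k3, cin, k3)
        P[[paste0(nm, ".Wp")]] <- he_init_(cin, blk$channels, cin)
      } else {
        cg <- cin %/% blk$groups
        co <- blk$channels %/% blk$groups
        P[[paste0(nm, ".Wg")]] <-
          lapply(seq_len(blk$groups), function(g) he_init_(cg * k3, co, cg * k3))
      }
      P[[paste0(nm, ".b")]] <- rep(0, blk$channels)
      add_bn(nm, blk$channels)
      cin <- blk$channels
    }
    din <- prod(config$final_dims) * config$final_channels
    for (i in 1:2) {
      nm <- sprintf("fc%d", i)
      dout <- config$fc_sizes[i]
      P[[paste0(nm, ".W")]] <- he_init_(din, dout, din)
      P[[paste0(nm, ".b")]] <- rep(0, dout)
      add_bn(nm, dout)
      din <- dout
    }
    P[["out.W"]] <- he_init_(4L, 1L, 4L)
    P[["out.b"]] <- 0
  })
  structure(list(config = config, params = P, bn = B, history = NULL,
                 trained = FALSE),
            class = "tmask_cnn")
}

#' @export
print.tmask_cnn <- function(x, ...) {
  cat(sprintf("<tmask_cnn> input %s, %d parameters%s\n",
              paste(x$config$input_dim, collapse = "x"), n_params(x),
              if (x$trained) sprintf(", trained %d epochs", nrow(x$history))
              else " (untrained)"))
  invisible(x)
}

#' Total number of trainable parameters of a model
#' @param model A [build_cnn()] result.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) {
    if (is.list(p)) sum(lengths(p)) else length(p)
  }, numeric(1)))
}

# One conv block: convolution (by kind) -> BN -> ELU -> [max-pool] -> dropout.
conv_block_fwd_ <- function(x, dims, n, nm, kind, pool, groups, P, B,
                            training, drop, k) {
  cv <- switch(kind,
    conv = conv3_fwd(x, dims, n, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]], k),
    separable = sepconv3_fwd(x, dims, n, P[[paste0(nm, ".Wd")]],
                             P[[paste0(nm, ".Wp")]], P[[paste0(nm, ".b")]], k),
    grouped = groupconv3_fwd(x, dims, n, P[[paste0(nm, ".Wg")]],
                             P[[paste0(nm, ".b")]], k, groups))
  bn <- bn_fwd(cv$out, P[[paste0(nm, ".gamma")]], P[[paste0(nm, ".beta")]],
               training, B[[nm]])
  el <- elu_fwd(bn$out)
  if (pool) {
    pl <- maxpool_fwd(el$out, dims, n)
    out <- pl$out; odims <- pl$dims; pcache <- pl$cache
  } else {
    out <- el$out; odims <- dims; pcache <- NULL
  }
  dr <- dropout_fwd(out, drop, training)
  list(out = dr$out, dims = odims, bn_state = bn$state,
       cache = list(conv = cv$cache, bn = bn$cache, elu = el$cache,
                    pool = pcache, drop = dr$cache, kind = kind, nm = nm))
}

conv_block_bwd_ <- function(dout, cache, G, need_dx = TRUE) {
  dout <- dropout_bwd(dout, cache$drop)
  if (!is.null(cache$pool)) dout <- maxpool_bwd(dout, cache$pool)
  dout <- elu_bwd(dout, cache$elu)
  bb <- bn_bwd(dout, cache$bn)
  add_grad_(G, paste0(cache$nm, ".gamma"), bb$dgamma)
  add_grad_(G, paste0(cache$nm, ".beta"), bb$dbeta)
  cb <- switch(cache$kind,
    conv = conv3_bwd(bb$dx, cache$conv, need_dx),
    separable = sepconv3_bwd(bb$dx, cache$conv, need_dx),
    grouped = groupconv3_bwd(bb$dx, cache$conv, need_dx))
  if (cache$kind == "conv") {
    add_grad_(G, paste0(cache$nm, ".W"), cb$dW)
  } else if (cache$kind == "separable") {
    add_grad_(G, paste0(cache$nm, ".Wd"), cb$dWd)
    add_grad_(G, paste0(cache$nm, ".Wp"), cb$dWp)
  } else {
    add_grad_(G, paste0(cache$nm, ".Wg"), cb$dWg)
  }
  add_grad_(G, paste0(cache$nm, ".b"), cb$db)
  cb$dx
}

add_grad_ <- function(G, nm, val) {
  if (is.null(G[[nm]])) {
    G[[nm]] <- val
  } else if (is.list(val)) {
    G[[nm]] <- Map(`+`, G[[nm]], val)
  } else {
    G[[nm]] <- G[[nm]] + val
  }
  invisible(NULL)
}

# Full forward pass. x is the (n*V) x 1 stacked input matrix.
cnn_forward <- function(model, x, n, training = FALSE) {
  cfg <- model$config
  P <- model$params
  B <- model$bn
  k <- cfg$kernel
  drate <- if (training) cfg$dropout_rate else 0
  bn_new <- list()
  streams <- vector("list", 2L)
  sdims <- NULL
  for (s in 1:2) {
    pnm <- if (cfg$share_stream_weights) 1L else s
    xs <- x; dims <- cfg$input_dim
    blocks <- vector("list", 2L)
    for (b in 1:2) {
      nm <- sprintf("s%d.b%d", pnm, b)
      blk <- conv_block_fwd_(xs, dims, n, nm, "conv", TRUE, NULL, P, B,
                             training, drate, k)
      xs <- blk$out; dims <- blk$dims
      bn_new[[nm]] <- blk$bn_state
      blocks[[b]] <- blk$cache
    }
    streams[[s]] <- list(out = xs, blocks = blocks)
    sdims <- dims
  }
  z <- cbind(streams[[1]]$out, streams[[2]]$out)
  concat <- list(x = z, dims = sdims,
                 split = c(ncol(streams[[1]]$out), ncol(streams[[2]]$out)))
  # add-block: conv -> BN -> residual add -> ELU -> dropout
  acv <- conv3_fwd(z, sdims, n, P[["add.W"]], P[["add.b"]], k)
  abn <- bn_fwd(acv$out, P[["add.gamma"]], P[["add.beta"]], training, B[["add"]])
  bn_new[["add"]] <- abn$state
  ael <- elu_fwd(abn$out + z)
  adr <- dropout_fwd(ael$out, drate, training)
  xt <- adr$out; dims <- sdims
  add_cache <- list(conv = acv$cache, bn = abn$cache, elu = ael$cache,
                    drop = adr$cache)
  trunk <- vector("list", length(cfg$trunk_blocks))
  for (t in seq_along(cfg$trunk_blocks)) {
    blk_spec <- cfg$trunk_blocks[[t]]
    nm <- sprintf("t%d", t)
    blk <- conv_block_fwd_(xt, dims, n, nm, blk_spec$kind, blk_spec$pool,
                           blk_spec$groups, P, B, training, drate, k)
    xt <- blk$out; dims <- blk$dims
    bn_new[[nm]] <- blk$bn_state
    trunk[[t]] <- blk$cache
  }
  fl <- flatten_fwd(xt, dims, n)
  xf <- fl$out
  fc <- vector("list", 2L)
  for (i in 1:2) {
    nm <- sprintf("fc%d", i)
    de <- dense_fwd(xf, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]])
    bn <- bn_fwd(de$out, P[[paste0(nm, ".gamma")]], P[[paste0(nm, ".beta")]],
                 training, B[[nm]])
    bn_new[[nm]] <- bn$state
    el <- elu_fwd(bn$out)
    dr <- dropout_fwd(el$out, drate, training)
    xf <- dr$out
    fc[[i]] <- list(dense = de$cache, bn = bn$cache, elu = el$cache,
                    drop = dr$cache, nm = nm)
  }
  ot <- dense_fwd(xf, P[["out.W"]], P[["out.b"]])
  logit <- as.vector(ot$out)
  list(logit = logit, prob = plogis(logit), bn = bn_new,
       caches = list(streams = streams, concat = concat, add = add_cache,
                     trunk = trunk, flat = fl$cache, fc = fc, out = ot$cache),
       n = n)
}

# Backward pass from d(loss)/d(logit). Returns parameter gradients; when
# upto = "concat", stops there and also returns the gradient w.r.t. the
# concatenated activation maps (used by grad-CAM).
cnn_backward <- function(model, fw, dlogit, upto = NULL) {
  cfg <- model$config
  G <- new.env(parent = emptyenv())
  cc <- fw$caches
  d <- dense_bwd(matrix(dlogit, ncol = 1L), cc$out)
  add_grad_(G, "out.W", d$dW); add_grad_(G, "out.b", d$db)
  dx <- d$dx
  for (i in 2:1) {
    f <- cc$fc[[i]]
    dx <- dropout_bwd(dx, f$drop)
    dx <- elu_bwd(dx, f$elu)
    bb <- bn_bwd(dx, f$bn)
    add_grad_(G, paste0(f$nm, ".gamma"), bb$dgamma)
    add_grad_(G, paste0(f$nm, ".beta"), bb$dbeta)
    d <- dense_bwd(bb$dx, f$dense)
    add_grad_(G, paste0(f$nm, ".W"), d$dW)
    add_grad_(G, paste0(f$nm, ".b"), d$db)
    dx <- d$dx
  }
  dx <- flatten_bwd(dx, cc$flat)
  for (t in rev(seq_along(cc$trunk)))
    dx <- conv_block_bwd_(dx, cc$trunk[[t]], G)
  # add-block
  dx <- dropout_bwd(dx, cc$add$drop)
  dsum <- elu_bwd(dx, cc$add$elu)
  bb <- bn_bwd(dsum, cc$add$bn)
  add_grad_(G, "add.gamma", bb$dgamma); add_grad_(G, "add.beta", bb$dbeta)
  cb <- conv3_bwd(bb$dx, cc$add$conv)
  add_grad_(G, "add.W", cb$dW); add_grad_(G, "add.b", cb$db)
  dz <- cb$dx + dsum                       # residual path
  if (identical(upto, "concat"))
    return(list(grads = as.list(G), dconcat = dz))
  sp <- cc$concat$split
  dstream <- list(dz[, seq_len(sp[1]), drop = FALSE],
                  dz[, sp[1] + seq_len(sp[2]), drop = FALSE])
  for (s in 1:2) {
    dxs <- dstream[[s]]
    for (b in 2:1)
      dxs <- conv_block_bwd_(dxs, cc$streams[[s]]$blocks[[b]], G,
                             need_dx = (b > 1L))
  }
  list(grads = as.list(G), dconcat = NULL)
}

# Stack the cohort volumes into the (n*V) x 1 matrix layout of the engine.
stack_to_mat <- function(stack) {
  V <- as.integer(prod(stack$dims))
  matrix(as.vector(vapply(stack$volumes, as.vector, numeric(V))), ncol = 1L)
}

#' Predict class-1 probabilities
#'
#' Inference is deterministic: dropout is off and batch normalization uses
#' its running statistics, so results are independent of batch composition.
#'
#' @param model A trained `tmask_cnn` or `tmask_linear` classifier.
#' @param stack A [volume_stack()] (already masked, for masked models).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), one per subject.
#' @export
predict_proba <- function(model, stack, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.tmask_cnn <- function(model, stack, ...) {
  if (!identical(stack$dims, model$config$input_dim))
    abort("inconsistent grid: input shape differs from the model input.",
          class = "tmasking_grid_error")
  n <- length(stack$volumes)
  V <- as.integer(prod(stack$dims))
  x <- stack_to_mat(stack)
  out <- numeric(n)
  bs <- 8L
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    rows <- as.vector(vapply(idx, function(s) (s - 1L) * V + seq_len(V),
                             integer(V)))
    fw <- cnn_forward(model, x[rows, , drop = FALSE], length(idx),
                      training = FALSE)
    out[idx] <- fw$prob
  }
  out
}
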