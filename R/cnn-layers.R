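# Layer primitives for the 3D CNN engine.
#
# Spatial activations are (n_samples * n_voxels) x n_channels matrices with
# voxels in R array order and samples stacked along rows; dense activations
# are n_samples x n_features matrices. Every *_fwd returns list(out, cache)
# and the matching *_bwd consumes (dout, cache) and returns the input
# gradient plus parameter gradients.

conv3_fwd <- function(x, dims, n, W, b, k) {
  out <- cpp_conv3_fwd(x, as.integer(dims), n, W, b, k)
  list(out = out, cache = list(x = x, W = W, dims = dims, n = n, k = k))
}

conv3_bwd <- function(dout, cache, need_dx = TRUE) {
  r <- cpp_conv3_bwd(cache$x, dout, as.integer(cache$dims), cache$n,
                     cache$W, cache$k, need_dx)
  list(dx = r$dx, dW = r$dW, db = r$db)
}

sepconv3_fwd <- function(x, dims, n, Wd, Wp, b, k) {
  outd <- cpp_dwconv3_fwd(x, as.integer(dims), n, Wd, k)
  out <- outd %*% Wp
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, outd = outd, Wd = Wd, Wp = Wp,
                               dims = dims, n = n, k = k))
}

sepconv3_bwd <- function(dout, cache, need_dx = TRUE) {
  dWp <- crossprod(cache$outd, dout)
  db <- colSums(dout)
  doutd <- tcrossprod(dout, cache$Wp)
  r <- cpp_dwconv3_bwd(cache$x, doutd, as.integer(cache$dims), cache$n,
                       cache$Wd, cache$k, need_dx)
  list(dx = r$dx, dWd = r$dWd, dWp = dWp, db = db)
}

groupconv3_fwd <- function(x, dims, n, Wg, b, k, groups) {
  C <- ncol(x)
  cg <- C %/% groups
  outs <- vector("list", groups)
  for (g in seq_len(groups)) {
    xg <- x[, (g - 1L) * cg + seq_len(cg), drop = FALSE]
    outs[[g]] <- cpp_conv3_fwd(xg, as.integer(dims), n, Wg[[g]],
                               numeric(ncol(Wg[[g]])), k)
  }
  out <- do.call(cbind, outs)
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, Wg = Wg, dims = dims, n = n, k = k,
                               Cin = C, groups = groups))
}

groupconv3_bwd <- function(dout, cache, need_dx = TRUE) {
  groups <- cache$groups
  cg <- cache$Cin %/% groups
  co <- ncol(dout) %/% groups
  dWg <- vector("list", groups)
  dxs <- vector("list", groups)
  for (g in seq_len(groups)) {
    xg <- cache$x[, (g - 1L) * cg + seq_len(cg), drop = FALSE]
    dg <- dout[, (g - 1L) * co + seq_len(co), drop = FALSE]
    r <- cpp_conv3_bwd(xg, dg, as.integer(cache$dims), cache$n,
                       cache$Wg[[g]], cache$k, need_dx)
    dWg[[g]] <- r$dW
    if (need_dx) dxs[[g]] <- r$dx
  }
  list(dx = if (need_dx) do.call(cbind, dxs) else NULL, dWg = dWg,
       db = colSums(dout))
}

rows_rep_ <- function(v, n) rep(v, each = n)

bn_fwd <- function(x, gamma, beta, training, state, momentum = 0.1,
                   eps = 1e-5) {
  if (training) {
    m <- colMeans(x)
    v <- colMeans(x^2) - m^2
    state$mean <- (1 - momentum) * state$mean + momentum * m
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    m <- state$mean
    v <- state$var
  }
  istd <- 1 / sqrt(v + eps)
  N <- nrow(x)
  xhat <- (x - rows_rep_(m, N)) * rows_rep_(istd, N)
  out <- xhat * rows_rep_(gamma, N) + rows_rep_(beta, N)
  list(out = out, state = state,
       cache = list(xhat = xhat, istd = istd, gamma = gamma,
                    training = training))
}

bn_bwd <- function(dout, cache) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  N <- nrow(dout)
  dxhat <- dout * rows_rep_(cache$gamma, N)
  if (cache$training) {
    dx <- (dxhat - rows_rep_(colSums(dxhat) / N, N) -
             cache$xhat * rows_rep_(colSums(dxhat * cache$xhat) / N, N)) *
      rows_rep_(cache$istd, N)
  } else {
    dx <- dxhat * rows_rep_(cache$istd, N)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu_fwd <- function(x) {
  neg <- x < 0
  out <- x
  out[neg] <- expm1(x[neg])
  grad <- array(1, dim(x))
  grad[neg] <- out[neg] + 1
  list(out = out, cache = grad)
}

elu_bwd <- function(dout, cache) dout * cache

dropout_fwd <- function(x, rate, training) {
  if (!training || rate == 0)
    return(list(out = x, cache = NULL))
  m <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(out = x * m, cache = m)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

maxpool_fwd <- function(x, dims, n) {
  r <- cpp_maxpool3(x, as.integer(dims), n)
  list(out = r$out, dims = dims %/% 2L,
       cache = list(idx = r$idx, nrow_in = nrow(x)))
}

maxpool_bwd <- function(dout, cache) {
  cpp_maxpool3_bwd(dout, cache$idx, cache$nrow_in)
}

dense_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, W = W))
}

dense_bwd <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# (n*V x C) spatial matrix -> (n x V*C) dense matrix, and back.
flatten_fwd <- function(x, dims, n) {
  V <- prod(dims)
  a <- array(x, c(V, n, ncol(x)))
  list(out = matrix(aperm(a, c(2, 1, 3)), n, V * ncol(x)),
       cache = list(V = V, n = n, C = ncol(x)))
}

flatten_bwd <- function(dout, cache) {
  a <- array(dout, c(cache$n, cache$V, cache$C))
  matrix(aperm(a, c(2, 1, 3)), cache$V * cache$n, cache$C)
}
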