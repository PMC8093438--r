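# One-axis linear interpolation operator (n_out x n_in), pixel-center
# aligned with edge clamping; used axis-by-axis for trilinear upsampling.
interp_matrix_ <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  i0 <- pmin(floor(src), n_in - 1L)
  if (n_in == 1L) i0 <- rep(1L, n_out)
  f <- src - i0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), i0)] <- W[cbind(seq_len(n_out), i0)] + (1 - f)
  W[cbind(seq_len(n_out), pmin(i0 + 1L, n_in))] <-
    W[cbind(seq_len(n_out), pmin(i0 + 1L, n_in))] + f
  W
}

#' Trilinear upsampling of a 3D grid
#'
#' @param arr Numeric 3D array.
#' @param out_dims Target length-3 dimensions.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return The resampled 3D array.
#' @export
upsample_grid <- function(arr, out_dims, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  mats <- lapply(1:3, function(a) {
    W <- interp_matrix_(d[a], out_dims[a])
    if (method == "nearest") {
      W2 <- matrix(0, nrow(W), ncol(W))
      W2[cbind(seq_len(nrow(W)), max.col(W, ties.method = "first"))] <- 1
      W2
    } else W
  })
  v <- array(mats[[1]] %*% matrix(arr, d[1]), c(out_dims[1], d[2], d[3]))
  v <- aperm(v, c(2, 1, 3))
  v <- array(mats[[2]] %*% matrix(v, d[2]), c(out_dims[2], out_dims[1], d[3]))
  v <- aperm(v, c(2, 1, 3))
  v <- aperm(v, c(3, 2, 1))
  v <- array(mats[[3]] %*% matrix(v, d[3]),
             c(out_dims[3], out_dims[2], out_dims[1]))
  aperm(v, c(3, 2, 1))
}

#' 3D grad-CAM heat-map at the concatenate layer
#'
#' Computes the gradient of the scalar objective with respect to the
#' activation maps of the channel-concatenation layer (the first layer
#' merging the two input streams), averages it spatially per channel to
#' obtain channel weights, forms the rectified channel-weighted activation
#' sum, upsamples it trilinearly to the input shape and max-normalizes it
#' to \[0, 1\] (an all-zero map is left as zeros). The model is run in
#' inference mode, so repeated calls give identical maps.
#'
#' @param model A trained `tmask_cnn`.
#' @param volume Numeric 3D array (a masked input volume).
#' @param layer_name Only `"concat"` is available in this architecture.
#' @param target `"loss"` (cross-entropy at `label`; default) or
#'   `"logit"` (the raw class score).
#' @param label True 0/1 label used by the `"loss"` target.
#' @param upsample `"trilinear"` or `"nearest"`.
#' @return An object of class `heat_map`: list with `grid` (3D array in
#'   \[0,1\], input shape), `layer`, `target`.
#' @export
grad_cam <- function(model, volume, layer_name = "concat",
                     target = c("loss", "logit"), label = 1L,
                     upsample = c("trilinear", "nearest")) {
  target <- match.arg(target)
  upsample <- match.arg(upsample)
  if (!identical(layer_name, "concat"))
    abort(sprintf("unknown layer '%s': the spatial merge layer is 'concat'.",
                  layer_name), class = "tmasking_param_error")
  if (!identical(dim(volume), model$config$input_dim))
    abort("inconsistent grid: volume shape differs from the model input.",
          class = "tmasking_grid_error")
  x <- matrix(as.vector(volume), ncol = 1L)
  fw <- cnn_forward(model, x, 1L, training = FALSE)
  dlogit <- if (target == "loss") fw$prob - as.numeric(label) else 1
  bw <- cnn_backward(model, fw, dlogit, upto = "concat")
  A <- fw$caches$concat$x
  w <- colMeans(bw$dconcat)
  cam <- pmax(as.vector(A %*% w), 0)
  cam <- array(cam, fw$caches$concat$dims)
  cam <- upsample_grid(cam, model$config$input_dim, method = upsample)
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  structure(list(grid = cam, layer = layer_name, target = target),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map:%s> %s grid, mass %.3g\n", x$layer,
              paste(dim(x$grid), collapse = "x"), sum(x$grid)))
  invisible(x)
}

#' Heat concentration inside a region
#'
#' Ratio of mean heat inside a region to mean heat outside it; values
#' above 1 indicate the saliency map focuses on the region. If all heat
#' lies inside the region the ratio is `Inf`.
#'
#' @param heat A [grad_cam()] heat-map.
#' @param region A non-empty, non-full [binary_mask()] of the same shape.
#' @return A non-negative scalar (possibly `Inf`).
#' @export
heat_region_contrast <- function(heat, region) {
  if (!identical(dim(heat$grid), dim(region$grid)))
    abort("inconsistent grid: heat-map and region differ in shape.",
          class = "tmasking_grid_error")
  inside <- region$grid != 0
  if (!any(inside) || all(inside))
    abort("degenerate region: must be non-empty and not cover the grid.",
          class = "tmasking_mask_error")
  mi <- mean(heat$grid[inside])
  mo <- mean(heat$grid[!inside])
  if (mo == 0) return(if (mi > 0) Inf else 1)
  mi / mo
}
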