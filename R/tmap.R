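#' Voxel-wise two-sample t-map on training data
#'
#' Computes the absolute voxel-wise two-sample t statistic between the two
#' label groups of a training cohort, after Gaussian smoothing of each
#' volume. Two modes are provided:
#'
#' * `"standard"` (default): the equal-variance two-sample t statistic
#'   \eqn{|\mu_0-\mu_1| / \sqrt{s_p^2 (1/n_0 + 1/n_1)}} with pooled
#'   variance \eqn{s_p^2} on \eqn{n_0+n_1-2} degrees of freedom. Its null
#'   distribution is the textbook t distribution, which makes thresholds on
#'   a scale like \[0, 8\] directly interpretable.
#' * `"literal"`: the effect-size-like quantity
#'   \eqn{|\mu_0-\mu_1| / \sqrt{0.5(\sigma_0^2+\sigma_1^2)}}, i.e. the mean
#'   difference scaled by the root average group variance without the
#'   sample-size factor.
#'
#' Sample standard deviations use divisor n-1 in both modes. Voxels outside
#' the brain support, or where both group variances are zero, are set to 0,
#' so the map is non-negative everywhere and zero off-support.
#'
#' To avoid leakage, callers must pass **training subjects only**: the
#' statistic uses the labels, and any validation/test subject in `stack`
#' would leak outcome information into feature selection.
#'
#' @param stack A [volume_stack()] containing training subjects of both
#'   classes, at least 2 per class.
#' @param brain_mask Optional [binary_mask()] restricting the support.
#' @param fwhm_mm Gaussian smoothing FWHM in mm applied to each volume
#'   before the test (default 6); 0 disables smoothing.
#' @param mode `"standard"` or `"literal"` (see above).
#' @return An object of class `tmap`: list with `grid` (3D non-negative
#'   array), `mode`, `fwhm_mm`, `n0`, `n1`, `support` (0/1 array or NULL),
#'   `voxel_sizes_mm`, `affine`.
#' @export
compute_tmap <- function(stack, brain_mask = NULL, fwhm_mm = 6,
                         mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  g0 <- which(stack$labels == 0L)
  g1 <- which(stack$labels == 1L)
  if (length(g0) == 0L || length(g1) == 0L)
    abort("one-group error: both classes must be present.",
          class = "tmasking_onegroup_error")
  if (length(g0) < 2L || length(g1) < 2L)
    abort("insufficient samples: need at least 2 subjects per group.",
          class = "tmasking_samples_error")
  vols <- stack$volumes
  if (fwhm_mm > 0)
    vols <- lapply(vols, smooth_volume, fwhm_mm = fwhm_mm,
                   voxel_sizes_mm = stack$voxel_sizes_mm)
  V <- as.integer(prod(stack$dims))
  X <- matrix(vapply(vols, as.vector, numeric(V)), nrow = V)
  n0 <- length(g0); n1 <- length(g1)
  mu0 <- rowMeans(X[, g0, drop = FALSE])
  mu1 <- rowMeans(X[, g1, drop = FALSE])
  v0 <- rowSums((X[, g0, drop = FALSE] - mu0)^2) / (n0 - 1)
  v1 <- rowSums((X[, g1, drop = FALSE] - mu1)^2) / (n1 - 1)
  denom2 <- if (mode == "literal") {
    0.5 * (v0 + v1)
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    sp2 * (1 / n0 + 1 / n1)
  }
  t <- ifelse(denom2 > 0, abs(mu0 - mu1) / sqrt(denom2), 0)
  if (!is.null(brain_mask)) t <- t * as.vector(brain_mask$grid)
  structure(
    list(grid = array(t, dim = stack$dims), mode = mode, fwhm_mm = fwhm_mm,
         n0 = n0, n1 = n1,
         support = if (is.null(brain_mask)) NULL else brain_mask$grid,
         voxel_sizes_mm = stack$voxel_sizes_mm, affine = stack$affine),
    class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("<tmap:%s> %s grid, fwhm %.1f mm, groups %d/%d, max t = %.3f\n",
              x$mode, paste(dim(x$grid), collapse = "x"), x$fwhm_mm,
              x$n0, x$n1, max(x$grid)))
  invisible(x)
}

#' Binarize a t-map at a threshold
#'
#' Selects voxels whose t statistic strictly exceeds the threshold (the
#' rejection rule t(v) > threshold), restricted to the brain support. At
#' threshold 0 this selects every support voxel with a defined, nonzero
#' statistic denominator, i.e. essentially the whole brain mask.
#'
#' @param tmap A [compute_tmap()] result.
#' @param threshold Non-negative scalar.
#' @return A [binary_mask()] with provenance `"tmask"`.
#' @export
threshold_mask <- function(tmap, threshold) {
  if (threshold < 0)
    abort("`threshold` must be non-negative.", class = "tmasking_param_error")
  g <- tmap$grid > threshold
  if (!is.null(tmap$support)) g <- g & (tmap$support != 0)
  binary_mask(g, "tmask", params = list(threshold = threshold))
}

#' Apply a binary mask to every volume of a cohort
#'
#' Elementwise product of each volume with the mask, preserving the spatial
#' layout (no vectorization or cropping); labels and subject ids are
#' untouched. This is the t-masking step proper: it is applied identically
#' to training, validation and test volumes.
#'
#' @param stack A [volume_stack()].
#' @param mask A [binary_mask()] on the same grid.
#' @return A masked `volume_stack`.
#' @export
apply_mask <- function(stack, mask) {
  if (!identical(dim(mask$grid), stack$dims))
    abort("inconsistent grid: mask shape differs from volumes.",
          class = "tmasking_grid_error")
  m <- mask$grid
  volume_stack(lapply(stack$volumes, function(v) v * m),
               stack$labels, stack$subject_ids, stack$voxel_sizes_mm,
               stack$affine)
}

#' Fraction of brain voxels retained by a mask
#'
#' @param mask A [binary_mask()] contained in the brain support.
#' @param brain_mask The brain [binary_mask()].
#' @return Scalar in \[0, 1\]: active(mask) / active(brain).
#' @export
selection_rate <- function(mask, brain_mask) {
  nb <- sum(brain_mask$grid)
  if (nb == 0L)
    abort("empty brain mask.", class = "tmasking_mask_error")
  sum(mask$grid) / nb
}

#' Perturb a t-map with additive Gaussian noise
#'
#' Adds i.i.d. Normal(0, sd) noise to the statistic within the brain
#' support, clipping negative perturbed values to 0 and leaving
#' off-support voxels at 0. Used as a robustness control emulating
#' misalignment/mislabeling corruption of the feature-selection statistic.
#'
#' @param tmap A [compute_tmap()] result.
#' @param sd Noise standard deviation (>= 0); the reference control uses 0.2.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   perturbation bit-for-bit.
#' @return A perturbed `tmap`.
#' @export
perturb_tmap_gaussian <- function(tmap, sd = 0.2, seed = NULL) {
  if (sd < 0)
    abort("`sd` must be non-negative.", class = "tmasking_param_error")
  out <- tmap
  if (sd == 0) return(out)
  with_seed_(seed, {
    sup <- if (is.null(tmap$support)) seq_along(tmap$grid) else
      which(tmap$support != 0)
    g <- tmap$grid
    g[sup] <- pmax(g[sup] + rnorm(length(sup), 0, sd), 0)
    out$grid <- g
  })
  out
}

#' Randomly knock active voxels out of a mask
#'
#' Each active voxel is independently turned off with probability `p`
#' (Bernoulli knockout); inactive voxels stay off. The reference control
#' uses p = 0.05 on the t-mask.
#'
#' @param mask A [binary_mask()].
#' @param p Knockout probability in \[0, 1\].
#' @param seed Optional integer seed for reproducibility.
#' @return A [binary_mask()] with provenance `"tmask_bernoulli"`.
#' @export
perturb_mask_bernoulli <- function(mask, p, seed = NULL) {
  if (p < 0 || p > 1)
    abort("`p` must be in [0, 1].", class = "tmasking_param_error")
  g <- mask$grid
  act <- which(g != 0)
  with_seed_(seed, {
    g[act] <- g[act] * (runif(length(act)) >= p)
  })
  binary_mask(g, "tmask_bernoulli",
              params = c(mask$params, list(p = p, seed = seed)))
}

#' Random voxel-wise feature-selection mask
#'
#' Draws one fixed mask over the brain support in which each voxel is kept
#' with probability 1 - p, the random analogue of a t-mask ("voxel-wise
#' dropout" drawn once per run and applied unchanged to train, validation
#' and test volumes).
#'
#' @param brain_mask The brain [binary_mask()].
#' @param p Turn-off probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A [binary_mask()] with provenance `"random"`.
#' @export
random_mask <- function(brain_mask, p, seed = NULL) {
  if (p < 0 || p > 1)
    abort("`p` must be in [0, 1].", class = "tmasking_param_error")
  g <- brain_mask$grid
  act <- which(g != 0)
  with_seed_(seed, {
    g[act] <- g[act] * (runif(length(act)) >= p)
  })
  binary_mask(g, "random", params = list(p = p, seed = seed))
}

#' Write a t-map as NIfTI with a JSON sidecar
#'
#' The statistic grid is stored as float32 NIfTI; a JSON sidecar records
#' mode, smoothing FWHM and group sizes.
#'
#' @param tmap A [compute_tmap()] result.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_tmap <- function(tmap, path) {
  write_volume(tmap$grid, tmap$affine, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(mode = tmap$mode, fwhm_mm = tmap$fwhm_mm, n0 = tmap$n0, n1 = tmap$n1),
    side, auto_unbox = TRUE)
  invisible(path)
}
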