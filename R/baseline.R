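#' Mean-intensity linear baseline classifier
#'
#' The single feature per subject is the mean intensity over the active
#' voxels of the feature-selection mask; a one-feature logistic regression
#' is fitted on the training subjects. Exposes the same
#' [predict_proba()] interface as the CNN.
#'
#' @param train_masked A masked training [volume_stack()].
#' @param mask The non-empty [binary_mask()] that produced it.
#' @return An object of class `tmask_linear`.
#' @export
linear_baseline <- function(train_masked, mask) {
  act <- which(mask$grid != 0)
  if (length(act) == 0L)
    abort("no features: the mask has no active voxels.",
          class = "tmasking_mask_error")
  feat <- vapply(train_masked$volumes, function(v) mean(as.vector(v)[act]),
                 numeric(1))
  df <- data.frame(y = train_masked$labels, x = feat)
  fit <- suppressWarnings(glm(y ~ x, family = binomial(), data = df))
  structure(list(fit = fit, active = act, dims = train_masked$dims),
            class = "tmask_linear")
}

#' @rdname predict_proba
#' @export
predict_proba.tmask_linear <- function(model, stack, ...) {
  if (!identical(stack$dims, model$dims))
    abort("inconsistent grid: input shape differs from the model input.",
          class = "tmasking_grid_error")
  feat <- vapply(stack$volumes,
                 function(v) mean(as.vector(v)[model$active]), numeric(1))
  p <- suppressWarnings(
    predict(model$fit, newdata = data.frame(x = feat), type = "response"))
  pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
}

#' @export
print.tmask_linear <- function(x, ...) {
  cat(sprintf("<tmask_linear> mean-intensity logistic baseline over %d voxels\n",
              length(x$active)))
  invisible(x)
}
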