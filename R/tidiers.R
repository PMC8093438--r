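#' Tidy a validation curve into long format
#'
#' @param x A `tmask_curve` from [run_configuration()].
#' @param ... Unused.
#' @return A tibble with columns `configuration`, `permutation`, `seed`,
#'   `grid`, `metric`, `value`.
#' @export
tidy.tmask_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(curve_metrics_),
                        names_to = "metric", values_to = "value") |>
    dplyr::select(dplyr::all_of(c("configuration", "permutation", "seed",
                                  "grid", "degenerate", "metric", "value")))
}

#' One-row summary of a validation curve
#'
#' The grid point with the highest mean test accuracy under average
#' cross-validation, with its mean test AUC and selection rate.
#'
#' @param x A `tmask_curve`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.tmask_curve <- function(x, ...) {
  agg <- aggregate_average_cv(x)
  best <- agg[which.max(agg$test_acc_mean), ]
  tibble(configuration = best$configuration, best_grid = best$grid,
         test_acc_mean = best$test_acc_mean,
         test_acc_sdm = best$test_acc_sdm,
         test_auc_mean = best$test_auc_mean,
         selection_rate_mean = best$selection_rate_mean,
         n_permutations = best$n_permutations)
}

#' Tidy the parameter inventory of a CNN
#'
#' @param x A `tmask_cnn`.
#' @param ... Unused.
#' @return A tibble with one row per parameter tensor: `name`, `shape`,
#'   `n`.
#' @export
tidy.tmask_cnn <- function(x, ...) {
  purrr::map_dfr(names(x$params), function(nm) {
    p <- x$params[[nm]]
    if (is.list(p)) {
      tibble(name = nm,
             shape = paste0(length(p), "x[",
                            paste(dim(p[[1]]), collapse = "x"), "]"),
             n = sum(lengths(p)))
    } else {
      tibble(name = nm,
             shape = paste(if (is.null(dim(p))) length(p) else dim(p),
                           collapse = "x"),
             n = length(p))
    }
  })
}

#' One-row summary of a CNN
#'
#' @param x A `tmask_cnn`.
#' @param ... Unused.
#' @return A one-row tibble with parameter count and, if trained, the
#'   number of epochs run, the restored best epoch and its validation
#'   loss/accuracy.
#' @export
glance.tmask_cnn <- function(x, ...) {
  out <- tibble(n_params = n_params(x), trained = x$trained)
  if (x$trained) {
    h <- x$history
    out$epochs <- nrow(h)
    out$best_epoch <- x$best_epoch
    out$val_loss <- h$val_loss[x$best_epoch]
    out$val_acc <- h$val_acc[x$best_epoch]
  }
  out
}

#' Plot a validation curve
#'
#' Mean metric per grid point across permutations with error bars showing
#' the standard deviation of the mean, one facet per metric.
#'
#' @param object A `tmask_curve`.
#' @param metrics Metrics to show (default accuracy and AUC curves).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmask_curve <- function(object,
                                 metrics = c("train_acc", "val_acc",
                                             "test_acc", "val_auc",
                                             "test_auc"), ...) {
  agg <- aggregate_average_cv(object)
  long <- agg |>
    tidyr::pivot_longer(dplyr::matches("_(mean|sdm)$"),
                        names_to = c("metric", ".value"),
                        names_pattern = "(.*)_(mean|sdm)") |>
    dplyr::filter(.data$metric %in% metrics)
  xlab <- if (identical(attr(object, "grid_var"), "p"))
    "turn-off probability p" else "t-mask threshold"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grid, y = .data$mean)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sdm,
                                          ymax = .data$mean + .data$sdm),
                             size = 0.2, color = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = xlab, y = "metric (mean ± sd of the mean)",
                  title = unique(long$configuration)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a t-map
#'
#' @param object A `tmap`.
#' @param slice Axial (third-axis) slice index; defaults to the middle.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmap <- function(object, slice = NULL, ...) {
  d <- dim(object$grid)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$t <- as.vector(object$grid[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("t-map (%s), axial slice %d",
                                  object$mode, slice)) +
    ggplot2::theme_minimal()
}
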