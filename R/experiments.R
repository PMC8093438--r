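#' Stratified train/validation/test split
#'
#' Randomly assigns subjects to train/validation/test subsets with the
#' given fractions, keeping the number of subjects per class equal in
#' every subset (balanced stratification). Each per-class subset size
#' must be integral, otherwise an error explains the smallest compatible
#' cohort sizes.
#'
#' @param labels Vector of 0/1 labels (balanced cohort).
#' @param fractions Length-3 fractions (train, val, test) summing to 1;
#'   default `c(0.6, 0.2, 0.2)`.
#' @param seed Optional integer seed; the same seed reproduces the split.
#' @return A tibble with columns `index`, `label`, `subset`
#'   (factor train/val/test).
#' @export
split_dataset <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  labels <- as.integer(labels)
  subset <- rep(NA_character_, length(labels))
  with_seed_(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      counts <- fractions * length(idx)
      if (max(abs(counts - round(counts))) > 1e-9)
        abort(sprintf(
          "split arithmetic error: %d subjects of class %d cannot be split as %s; choose a class size divisible accordingly.",
          length(idx), cl, paste(fractions, collapse = "/")),
          class = "tmasking_split_error")
      counts <- round(counts)
      idx <- sample(idx)
      subset[idx] <- rep(c("train", "val", "test"), counts)
    }
  })
  tibble(index = seq_along(labels), label = labels,
         subset = factor(subset, levels = c("train", "val", "test")))
}

#' Equally spaced threshold grid
#'
#' Default: 21 points spanning \[0, 8\] inclusive (step 0.4), with the
#' zero threshold corresponding to the entire brain mask and the upper
#' end typically leaving no surviving voxels.
#'
#' @param lo,hi Range endpoints, `lo < hi`.
#' @param n_points Number of points (>= 2).
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(lo = 0, hi = 8, n_points = 21) {
  if (!(lo < hi) || n_points < 2)
    abort("invalid threshold range.", class = "tmasking_param_error")
  seq(lo, hi, length.out = n_points)
}

#' Accuracy and ROC AUC of predicted probabilities
#'
#' Accuracy uses the fixed 0.5 probability cutoff. AUC is the probability
#' that a random positive outranks a random negative, ties counted 1/2
#' (the rank/Wilcoxon form, equal to the trapezoidal ROC area).
#'
#' @param probabilities Numeric vector of class-1 probabilities.
#' @param labels 0/1 labels of the same length; both classes must be
#'   present for the AUC.
#' @return A one-row tibble with `accuracy`, `auc`, `n`.
#' @export
evaluate <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L)
    abort("AUC undefined: both classes must be present.",
          class = "tmasking_onegroup_error")
  acc <- mean((probabilities > 0.5) == (labels == 1L))
  r <- rank(probabilities)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  tibble(accuracy = acc, auc = auc, n = length(labels))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`; two empty masks score 1 by convention.
#'
#' @param mask_a,mask_b [binary_mask()]s on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a$grid), dim(mask_b$grid)))
    abort("inconsistent grid: masks differ in shape.",
          class = "tmasking_grid_error")
  na <- sum(mask_a$grid); nb <- sum(mask_b$grid)
  if (na + nb == 0L) return(1)
  2 * sum(mask_a$grid * mask_b$grid) / (na + nb)
}

#' Performance enhancement (PE)
#'
#' Difference of two test accuracies (in percent), each estimated with
#' average cross-validation; negative PE means the model underperforms
#' the reference.
#'
#' @param acc_model,acc_reference Accuracies in percent, in \[0, 100\].
#' @return PE in percentage points.
#' @export
performance_enhancement <- function(acc_model, acc_reference) {
  stopifnot(acc_model >= 0, acc_model <= 100,
            acc_reference >= 0, acc_reference <= 100)
  acc_model - acc_reference
}

config_ids_ <- c("raw", "norm", "fs_cnn", "fs_linear", "fs_noise",
                 "fs_bernoulli", "fs_random")

#' Run one experimental configuration as a validation curve
#'
#' Reproduces the experimental design around t-masking: for each of
#' `n_permutations` random stratified splits, the t-map is computed on the
#' training subset only, transformed according to the configuration,
#' binarized at each grid point, applied to all three subsets, and the
#' configured classifier is trained and evaluated.
#'
#' Configurations:
#' * `raw`, `norm` — no feature selection; the whole-brain mask is applied
#'   (one grid point). On co-registered synthetic cohorts the two coincide;
#'   the distinction (unregistered vs spatially normalized inputs) only
#'   matters for real data.
#' * `fs_cnn` — t-mask thresholded at each grid value, CNN classifier.
#' * `fs_linear` — same masks, mean-intensity linear classifier.
#' * `fs_noise` — Gaussian noise (sd `noise_sd`, default 0.2) added to the
#'   t-map once per permutation before thresholding.
#' * `fs_bernoulli` — t-mask voxels knocked out i.i.d. with probability
#'   `bernoulli_p` (default 0.05) after thresholding.
#' * `fs_random` — a fixed random mask per permutation keeping each brain
#'   voxel with probability 1-p; the grid variable is p.
#'
#' Grid points whose mask is empty are recorded as chance-level metrics
#' with `degenerate = TRUE` rather than aborting the sweep, so curves
#' always materialize over the full grid.
#'
#' @param config_id One of `"raw"`, `"norm"`, `"fs_cnn"`, `"fs_linear"`,
#'   `"fs_noise"`, `"fs_bernoulli"`, `"fs_random"`.
#' @param cohort List with `stack` (a [volume_stack()]) and `brain_mask`
#'   (a [binary_mask()]), e.g. from [generate_cohort()] or [read_cohort()].
#' @param grid Numeric sweep grid: thresholds (default
#'   [threshold_grid()]) or, for `fs_random`, turn-off probabilities
#'   (default 21 points on \[0.01, 0.99\]). Ignored for `raw`/`norm`.
#' @param n_permutations Number of random split permutations (default 5).
#' @param seed Master integer seed, expanded deterministically into
#'   per-permutation seeds.
#' @param model_config A [cnn_config()]; default `cnn_preset("desk", dims)`.
#' @param schedule A [training_schedule()].
#' @param fwhm_mm Smoothing FWHM for the t-map (default 6 mm).
#' @param tmap_mode `"standard"` or `"literal"` t statistic.
#' @param fractions Split fractions (default 0.6/0.2/0.2).
#' @param noise_sd,bernoulli_p Perturbation parameters for the `fs_noise`
#'   and `fs_bernoulli` configurations.
#' @param normalize Apply per-volume [znormalize()] first (default TRUE).
#' @param verbose Print per-point progress.
#' @return A tibble of class `tmask_curve`: one row per (permutation, grid
#'   point) with selection rate, train/val/test accuracy and val/test AUC.
#' @export
run_configuration <- function(config_id, cohort, grid = NULL,
                              n_permutations = 5, seed = 1,
                              model_config = NULL,
                              schedule = training_schedule(),
                              fwhm_mm = 6, tmap_mode = "standard",
                              fractions = c(0.6, 0.2, 0.2),
                              noise_sd = 0.2, bernoulli_p = 0.05,
                              normalize = TRUE, verbose = FALSE) {
  config_id <- match.arg(config_id, config_ids_)
  stack <- cohort$stack
  brain <- cohort$brain_mask
  if (is.null(brain))
    abort("cohort must carry a brain mask.", class = "tmasking_mask_error")
  if (is.null(grid)) {
    grid <- switch(config_id,
                   raw = 0, norm = 0,
                   fs_random = seq(0.01, 0.99, length.out = 21),
                   threshold_grid())
  }
  if (config_id %in% c("raw", "norm")) grid <- grid[1]
  if (normalize) stack <- znormalize(stack)
  if (is.null(model_config)) model_config <- cnn_preset("desk", stack$dims)
  needs_tmap <- config_id %in% c("fs_cnn", "fs_linear", "fs_noise",
                                 "fs_bernoulli")
  rows <- list()
  for (i in seq_len(n_permutations)) {
    pseed <- as.integer(seed) + 7919L * (i - 1L)
    sp <- split_dataset(stack$labels, fractions, seed = pseed)
    tr <- stack_subset(stack, sp$subset == "train")
    va <- stack_subset(stack, sp$subset == "val")
    te <- stack_subset(stack, sp$subset == "test")
    tm <- NULL
    if (needs_tmap) {
      tm <- compute_tmap(tr, brain, fwhm_mm = fwhm_mm, mode = tmap_mode)
      if (config_id == "fs_noise")
        tm <- perturb_tmap_gaussian(tm, noise_sd, seed = pseed + 1L)
    }
    for (j in seq_along(grid)) {
      g <- grid[j]
      mask <- switch(config_id,
        raw = brain, norm = brain,
        fs_cnn = threshold_mask(tm, g),
        fs_linear = threshold_mask(tm, g),
        fs_noise = threshold_mask(tm, g),
        fs_bernoulli = perturb_mask_bernoulli(threshold_mask(tm, g),
                                              bernoulli_p,
                                              seed = pseed + 100L + j),
        fs_random = random_mask(brain, g, seed = pseed + 200L))
      srate <- selection_rate(mask, brain)
      if (mask_size(mask) == 0L) {
        rows[[length(rows) + 1L]] <- tibble(
          configuration = config_id, permutation = i, seed = pseed,
          grid = g, selection_rate = srate, degenerate = TRUE,
          train_acc = 0.5, val_acc = 0.5, test_acc = 0.5,
          val_auc = 0.5, test_auc = 0.5)
        next
      }
      mtr <- apply_mask(tr, mask)
      mva <- apply_mask(va, mask)
      mte <- apply_mask(te, mask)
      if (config_id == "fs_linear") {
        fit <- linear_baseline(mtr, mask)
      } else {
        sch <- schedule
        sch$seed <- pseed + 400L + j
        fit <- build_cnn(model_config, seed = pseed + 300L + j)
        fit <- train_cnn(fit, mtr, mva, sch)
      }
      etr <- evaluate(predict_proba(fit, mtr), mtr$labels)
      eva <- evaluate(predict_proba(fit, mva), mva$labels)
      ete <- evaluate(predict_proba(fit, mte), mte$labels)
      if (verbose)
        message(sprintf("%s perm %d grid %.3g: test acc %.3f (sel %.3f)",
                        config_id, i, g, ete$accuracy, srate))
      rows[[length(rows) + 1L]] <- tibble(
        configuration = config_id, permutation = i, seed = pseed,
        grid = g, selection_rate = srate, degenerate = FALSE,
        train_acc = etr$accuracy, val_acc = eva$accuracy,
        test_acc = ete$accuracy, val_auc = eva$auc, test_auc = ete$auc)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tmask_curve", class(out))
  attr(out, "grid_var") <- if (config_id == "fs_random") "p" else "threshold"
  out
}

curve_metrics_ <- c("train_acc", "val_acc", "test_acc", "val_auc", "test_auc",
                    "selection_rate")

#' Average cross-validation aggregation of a validation curve
#'
#' Per grid point, the arithmetic mean across permutations of each metric
#' together with its spread, reported as the standard deviation of the
#' mean (sd / sqrt(n_permutations)).
#'
#' @param curve A [run_configuration()] result (>= 2 permutations).
#' @return A tibble with one row per grid point: `<metric>_mean` and
#'   `<metric>_sdm` columns.
#' @export
aggregate_average_cv <- function(curve) {
  if (dplyr::n_distinct(curve$permutation) < 2L)
    abort("average cross-validation needs at least 2 permutations.",
          class = "tmasking_param_error")
  curve |>
    dplyr::group_by(.data$configuration, .data$grid) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(curve_metrics_),
                    list(mean = mean,
                         sdm = ~ sd(.x) / sqrt(length(.x)))),
      n_permutations = dplyr::n(), .groups = "drop")
}

#' Classical cross-validation selection from a validation curve
#'
#' Returns the test metrics of the (permutation, grid point) maximizing
#' validation accuracy; ties are broken by higher validation AUC, then by
#' lower grid value. Test metrics are never consulted in the selection.
#'
#' @param curve A [run_configuration()] result.
#' @return A one-row tibble with the selected `grid`, `permutation`, and
#'   its `test_acc` and `test_auc`.
#' @export
aggregate_classical_cv <- function(curve) {
  curve |>
    dplyr::arrange(dplyr::desc(.data$val_acc), dplyr::desc(.data$val_auc),
                   .data$grid) |>
    dplyr::slice(1L) |>
    dplyr::select(dplyr::all_of(c("configuration", "permutation", "grid",
                                  "test_acc", "test_auc")))
}

#' Write a validation curve as tidy CSV with a JSON run manifest
#'
#' `curve.csv` holds the long (tidy) form of the curve; `manifest.json`
#' records the configuration, grid, permutation seeds and package version.
#'
#' @param curve A [run_configuration()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_curve <- function(curve, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tidy(curve), file.path(dir, "curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(configuration = unique(curve$configuration),
         grid_var = attr(curve, "grid_var"),
         grid = sort(unique(curve$grid)),
         seeds = sort(unique(curve$seed)),
         package_version = as.character(utils::packageVersion("tmasking"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
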