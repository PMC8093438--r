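# tmasking

Voxel-wise **t-masking** feature selection for binary classification of
co-registered 3D intensity volumes (spatially normalized structural MRI
and the like), with an end-to-end synthetic validation pipeline.

## Who this is for

Neuroimaging and biomedical-imaging researchers who classify subjects from
aligned 3D volumes with a few hundred subjects and 10⁴–10⁶ voxels, and who
want a statistically grounded, leakage-safe way to discard uninformative
voxels before training a 3D convolutional network — plus the machinery to
quantify what that feature selection buys.

## The method

For every voxel *v*, a two-sample t statistic compares the group mean
intensities across the **training** subjects only, after Gaussian
smoothing (FWHM 6 mm by default):

    t(v) = |μ₀(v) − μ₁(v)| / sqrt(s_p²(v) · (1/n₀ + 1/n₁))      (standard mode)
    t(v) = |μ₀(v) − μ₁(v)| / sqrt(0.5 · (σ₀²(v) + σ₁²(v)))      (literal mode)

Voxels with `t(v) > τ` form the binary **t-mask**, which multiplies every
volume (train/validation/test alike) before classification; voxels at 0 in
the mask are treated as redundant features. The threshold τ is chosen from
validation curves over an equally spaced grid (default 21 points on
[0, 8]) across repeated stratified 60/20/20 permutations, aggregated as
*average* cross-validation (mean ± sd of the mean across permutations) or
*classical* cross-validation (test metrics of the best-on-validation
model). **PE** (performance enhancement) is the difference in average-CV
test accuracy between a model and a reference, in percentage points.

The package provides:

* NIfTI cohort I/O, per-volume intensity normalization, brain masks
  (`read_cohort()`, `znormalize()`);
* smoothed t-maps, thresholding, perturbation controls (Gaussian t-map
  noise, Bernoulli knockout, random masks) and mask application
  (`compute_tmap()`, `threshold_mask()`, `apply_mask()`, ...);
* a self-contained Siamese 3D CNN engine (two streams → channel
  concatenation → residual add-block → separable/grouped trunk → two FC
  blocks → logistic output) with Adam, decaying learning rate, batch norm,
  dropout, L2 and early stopping (`build_cnn()`, `train_cnn()`), plus a
  mean-intensity logistic baseline (`linear_baseline()`);
* the seven experimental configurations with validation-curve sweeps and
  both cross-validation aggregations (`run_configuration()`,
  `aggregate_average_cv()`, `aggregate_classical_cv()`,
  `performance_enhancement()`);
* 3D grad-CAM saliency at the concatenate layer (`grad_cam()`);
* a phantom generator planting group differences of exact per-voxel
  Cohen's d in ~10% of an ellipsoidal brain (`phantom_spec()`,
  `generate_cohort()`), used for quantitative recovery tests (Dice,
  type-I calibration).

Results are tibbles with `tidy()`, `glance()` and `autoplot()` methods. A
thin CLI over the same functions lives at `inst/cli/tmasking.R`
(`simulate`, `tmask`, `curve`).

## Worked example

```r
library(tmasking)

# a synthetic cohort: 40 + 40 subjects, 24^3 grid, planted per-voxel
# Cohen's d = 1.2 in ~10% of the brain
cohort <- generate_cohort(phantom_spec(grid_dims = c(24, 24, 24),
                                       effect_size = 1.2, seed = 1))

# threshold sweep of the t-masked linear model, 5 split permutations
curve <- run_configuration("fs_linear", cohort, grid = c(0, 2, 4, 6),
                           n_permutations = 5, seed = 1)
aggregate_average_cv(curve)[, c("grid", "selection_rate_mean",
                                "test_acc_mean", "test_acc_sdm")]
#>   grid selection_rate_mean test_acc_mean test_acc_sdm
#> 1    0               1.000         0.938       0.0198
#> 2    2               0.383         1.000       0.0000
#> 3    4               0.147         1.000       0.0000
#> 4    6               0.108         1.000       0.0000
```

Reading: at threshold 0 the classifier sees the whole brain and averages
signal with noise (mean test accuracy 0.938 ± 0.020 across the five
permutations); any t-mask that concentrates on the planted region (38.3%
of brain voxels at τ = 2 down to 10.8% at τ = 6) lifts mean test accuracy
to 1.000. `run_configuration("fs_cnn", ...)` runs the same sweep with the
3D CNN, `autoplot(curve)` draws the validation curves, and
`glance(curve)` reports the best grid point (here τ = 2, test accuracy
1.000).

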