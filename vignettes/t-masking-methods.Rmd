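---
title: "t-Masking: voxel-wise feature selection for 3D image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{t-Masking: voxel-wise feature selection for 3D image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tmasking)
```

## The problem

Binary classification of structural brain images — for example separating
very mild Alzheimer's disease from normal controls on spatially normalized
T1-weighted MRI — pits a few hundred subjects against hundreds of thousands
of voxels. Most voxels carry no class information; fed to a convolutional
network they act as structured noise that slows and destabilizes learning.
**t-Masking** is a data-driven feature-selection step that addresses this
with mass-univariate statistics: a voxel-wise two-sample t-test between the
groups, computed **on training subjects only**, thresholded into a binary
mask, and applied multiplicatively to every volume (training, validation
and test alike) before the classifier sees them. Because the mask preserves
spatial layout (no vectorization, no cropping), the convolutional
architecture still exploits local structure among the retained voxels.

## The statistic

For each voxel $v$, with per-group sample means $\mu_0(v), \mu_1(v)$ and
sample standard deviations $\sigma_0(v), \sigma_1(v)$ (divisor $n-1$), the
package offers two modes:

* **standard** (default): the equal-variance two-sample t statistic
  $t(v) = |\mu_0 - \mu_1| \, / \sqrt{s_p^2 (1/n_0 + 1/n_1)}$ with pooled
  variance $s_p^2$ on $n_0 + n_1 - 2$ degrees of freedom.
* **literal**: $t(v) = |\mu_0 - \mu_1| \, / \sqrt{0.5(\sigma_0^2 +
  \sigma_1^2)}$ — the same numerator scaled by the root mean group
  variance, without the sample-size factor; an effect-size-like quantity.

The two coincide up to the factor $\sqrt{n/2}$ for balanced groups. The
standard form is the default because its null distribution is the textbook
t distribution — a threshold grid over $[0, 8]$ then has a direct
probabilistic reading, and the type-I calibration test below applies to it
exactly. The literal form is retained for fidelity to formulations that
omit the sample-size factor; both are absolute-valued (two-sided) and both
set voxels with zero variance, or outside the brain support, to 0.

Each training volume is Gaussian-smoothed before the test (default FWHM
6 mm, converted per axis as $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$
voxels), the usual variance-pooling step of voxel-wise group analysis.
Smoothing is used *only* inside the t-test; the classifier receives
unsmoothed (masked) volumes. Boundary handling is nearest-edge replication,
so flat fields pass through exactly. The rejection rule is strict:
$t(v) > \tau$, so $\tau = 0$ selects essentially the whole brain mask and a
threshold above the map maximum selects nothing.

### Leakage

The t-map uses class labels, so computing it on anything but training
subjects would leak outcome information into feature selection.
`compute_tmap()` takes the training subset only; the test suite verifies
that permuting validation/test labels leaves the t-mask bit-identical, and
that classical cross-validation model selection never inspects test
metrics.

## Perturbation controls

Three controls probe how much of the benefit is attributable to the
statistic itself:

* `fs_noise`: i.i.d. Normal(0, 0.2) noise added to the t-map (within the
  brain, negatives clipped to 0) before thresholding — emulating
  misalignment or mislabeling corruption. The draw is taken once per
  permutation, so nesting of masks across the threshold grid is preserved.
* `fs_bernoulli`: after thresholding, each active voxel is knocked out
  independently with p = 0.05.
* `fs_random`: a mask over the brain keeping each voxel with probability
  1-p, drawn **once per permutation** and held fixed across subjects and
  epochs — a genuine feature-selection baseline rather than training-time
  dropout; the sweep variable is p.

The noise control is applied to the *statistic map* rather than to the
binary mask or the images; of the three readings this is the one that
matches a corruption of the feature-selection step itself, and it keeps
threshold sweeps well-defined on the perturbed map.

## The classifier

The package ships a compact, self-contained 3D CNN engine (direct C++
convolution kernels behind plain R training code). The topology is fixed:
the same masked volume enters **two parallel convolutional streams** (two
blocks each: convolution, batch normalization, ELU, 2×2×2 max-pooling,
dropout); their activation maps are merged along the channel axis (the
*concatenate* layer); an **add-block** (convolution + batch norm, residual
addition, ELU) follows; then a trunk of standard/**separable**/**grouped**
convolutional blocks, and two fully connected blocks ending in a
4-dimensional feature vector feeding a logistic output. Weights are
He-initialized; all convolutional and FC weights carry an L2 penalty
(default 5e-5); dropout is 0.1 everywhere.

Since the exact channel widths of the reference architecture are not
recoverable, the architecture is fully config-driven with two presets:
`paper-like` for ~MNI grids (91×109×91) and `desk` (two 2-channel stream
blocks, one separable 4-channel trunk block, FC 16→4) for 24³–48³ phantoms,
trainable in seconds on one CPU. Whether the two streams share weights is
ambiguous in the "Siamese" reading; `share_stream_weights = FALSE`
(independent streams, as in the parent model) is the default and the shared
variant is a flag.

Training minimizes binary cross-entropy plus the L2 term with Adam, batch
size 6 drawn by random permutation until the dataset is exhausted, under
the decaying schedule `lr(epoch) = base_lr * 0.3^(epoch/10)` (continuous
exponent; a stepped variant is available). Early stopping watches
validation loss with patience 10 and always restores the
best-validation-loss weights. With a fixed seed, training is
bit-reproducible; inference disables dropout and uses batch-norm running
statistics, so predictions are independent of batch composition.

**Desk-scale learning rate.** The reference base rate of 0.001 was tuned
for the full-size network on MNI-grid volumes. On the `desk` preset the
epoch budget is ~30 epochs of 8 mini-batches, and at base rate 0.001 the
schedule decays before the compact network converges. The desk-scale
experiments therefore use `base_lr = 0.01` with the same decay shape,
batch size and patience; `training_schedule()` keeps the reference
defaults.

The linear baseline (`linear_baseline()`) reduces each masked volume to a
single scalar — the mean intensity over active mask voxels — and fits a
one-feature logistic regression, exposing the same `predict_proba()`
interface.

## Experimental design

`run_configuration()` reproduces the surrounding experimental machinery:
stratified 60/20/20 splits balanced per class, the seven configurations
(`raw`, `norm`, `fs_cnn`, `fs_linear`, `fs_noise`, `fs_bernoulli`,
`fs_random`), a 21-point threshold grid over [0, 8] (step 0.4), five
random split permutations by default, and two aggregations:

* **average cross-validation** — per grid point, the mean across
  permutations with spread reported as the standard deviation of the mean;
* **classical cross-validation** — the test metrics of the (permutation,
  grid point) maximizing validation accuracy, ties broken by validation
  AUC and then by lower threshold (a deterministic, documented rule).

Accuracy uses a fixed 0.5 probability cutoff; AUC is the rank-form
probability that a positive outranks a negative with ties counted ½.
**PE** (performance enhancement) is the difference of two average-CV test
accuracies in percentage points. Grid points whose mask is empty are
recorded as chance-level with a `degenerate` flag so full curves always
materialize. On synthetic co-registered cohorts `raw` and `norm` coincide
by construction; the distinction (unregistered vs spatially normalized
input) is kept in the interface for real data.

## The phantom generator

`phantom_spec()`/`generate_cohort()` emulate the statistical structure of a
spatially normalized T1-w cohort without any real data: an ellipsoidal
brain (semi-axes ≈ 0.4 of the grid) filled with base intensity 1 plus a
fixed smoothed Gaussian random texture field (sd 0.5, FWHM 9 mm — a tissue
contrast typical of intensity-normalized MRI), shared by all subjects;
per-subject i.i.d. Normal(0, 0.2) noise; and two effect spheres jointly
covering ~10% of the brain in which group-1 subjects receive a uniform
intensity decrement of `effect_size * noise_sd`, so the per-voxel
in-region Cohen's d equals `effect_size` exactly in expectation. Defaults:
32³ grid at 3 mm voxels (so the 6 mm FWHM remains meaningful, σ ≈ 0.85
voxels), 40 subjects per group, d = 1.2.

The additive mean shift (atrophy-like hypointensity) was chosen over a
deformation model so that the planted effect size is exactly controlled
and recovery is quantitative (Dice between the t-mask and the ground-truth
region). Subject noise is spatially independent by default, which makes
the standard-mode null t-map exactly textbook-t distributed and enables a
sharp type-I calibration test at α = 0.01; a smoothed-noise option models
realistic spatial correlation but forfeits that exactness.

What the phantoms deliberately do **not** emulate: real anatomy and tissue
classes, registration error, scanner/site effects, age and sex covariates,
and deformation-based (rather than intensity-based) group differences.
Passing the synthetic suites therefore shows that the pipeline is
implemented correctly and behaves as designed under its own assumptions —
not that the measured effect sizes or accuracies transfer to any real
cohort.

## Numerical choices and degenerate inputs

* Intensity normalization is per volume (mean 0, sd 1, population-sd
  convention), over the whole volume by default or over a brain mask if
  supplied; constant volumes are rejected. Normalization is per-subject
  and label-free, so it cannot leak.
* Zero-variance voxels get t = 0 (excluded) rather than NaN/Inf.
* Gaussian kernels are truncated at 4σ and renormalized to sum 1.
* Batch norm uses ε = 1e-5 and running-stat momentum 0.1.
* Dice of two empty masks is 1 by convention; `heat_region_contrast()`
  returns `Inf` when all heat falls inside the region.
* Empty masks during sweeps yield chance-level metrics with a flag, not an
  abort; `linear_baseline()` on an empty mask is an error.
* Master seeds expand deterministically into per-permutation seeds
  (fixed integer offsets), and every seeded helper restores the caller's
  RNG state.

## A small worked run

```{r curve, eval = FALSE}
# ~1 minute on one CPU; a full 21-point, 5-permutation CNN sweep takes
# tens of minutes and is what scripts/acceptance.R runs in reduced form.
cohort <- generate_cohort(phantom_spec(grid_dims = c(24, 24, 24),
                                       effect_size = 1.2, seed = 1))
curve <- run_configuration("fs_linear", cohort, n_permutations = 5,
                           seed = 1)
aggregate_average_cv(curve)
autoplot(curve)
```

## Problem sizes used by the automated checks

The test-suite and acceptance-script experiments run at desk scale, chosen
so the full pipeline (not a mock) executes end to end: t-map oracle checks
on 8³ cohorts of 10 + 10 subjects; calibration and recovery phantoms at
32³ with 40 subjects per group; the feature-selection benefit on 24³
phantoms (d = 1.0, 10% relevant fraction, 40 per group) with the `desk`
CNN, 5 permutations over a reduced threshold grid in the test suite and 3
permutations over {0, 3, 4.5} in the acceptance script. These sizes keep
every quantity genuinely computed while the whole suite stays in the
minutes range.

## Known limitations

* The CNN engine is single-threaded and CPU-bound; the `paper-like` preset
  builds and runs but full-size training is far slower than a GPU
  framework would be.
* Thresholding raw t scores replaces formal multiple-testing control by
  design (the validation curve takes that role); FDR-corrected or
  permutation-maximal thresholds are out of scope.
* Stratification is by label only; covariate matching (age/sex) is not
  re-implemented.
* Fig.-style stepped learning-rate decay, transfer learning, augmentation
  and clinical-covariate streams are intentionally absent.
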