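#' Parameterize a synthetic phantom cohort
#'
#' Describes a cohort of co-registered, T1-like 3D brain phantoms: an
#' ellipsoidal "brain" filled with a fixed smoothed random-field tissue
#' texture, per-subject i.i.d. Gaussian noise, and a compact set of effect
#' regions (spheres inside the brain) in which group-1 subjects receive a
#' uniform intensity decrement of controlled per-voxel effect size
#' (Cohen's d), emulating atrophy-like hypointensity in a small fraction
#' (~10% by default) of the brain.
#'
#' Default geometry: a 32^3 grid at 3 mm isotropic voxels with brain
#' semi-axes 0.42/0.38/0.40 of the grid, and two effect spheres jointly
#' sized to cover `target_fraction` of the brain (70%/30% volume split,
#' fixed off-center positions). The texture field sd and subject noise sd
#' set a tissue-contrast-to-noise ratio typical of intensity-normalized
#' structural MRI; the group effect is `effect_size * noise_sd`, so the
#' per-voxel in-region Cohen's d equals `effect_size` by construction.
#'
#' @param grid_dims Length-3 integer grid dimensions (default 32^3).
#' @param voxel_size_mm Isotropic voxel size in mm (default 3).
#' @param brain_semiaxes Ellipsoid semi-axes in voxels; default
#'   `c(0.42, 0.38, 0.40) * grid_dims`.
#' @param texture_sd Sd of the shared tissue texture field (default 0.5).
#' @param texture_fwhm_mm Smoothing FWHM of the texture field (default 9).
#' @param noise_sd Per-subject i.i.d. noise sd (default 0.2).
#' @param target_fraction Desired |effect region| / |brain| (default 0.10).
#' @param effect_size Per-voxel Cohen's d of the group-1 decrement
#'   (default 1.2).
#' @param n_per_group Subjects per group (default 40, >= 2).
#' @param regions Optional list of spheres `list(center=, radius=)` in voxel
#'   coordinates overriding the derived default regions.
#' @param smooth_noise_fwhm_mm FWHM for optional smoothing of the subject
#'   noise field (default 0 = spatially independent noise, which keeps the
#'   null t-map distribution exactly textbook t).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(32, 32, 32), voxel_size_mm = 3,
                         brain_semiaxes = NULL, texture_sd = 0.5,
                         texture_fwhm_mm = 9, noise_sd = 0.2,
                         target_fraction = 0.10, effect_size = 1.2,
                         n_per_group = 40, regions = NULL,
                         smooth_noise_fwhm_mm = 0, seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 8L),
            voxel_size_mm > 0, n_per_group >= 2, effect_size >= 0,
            target_fraction > 0, target_fraction < 1)
  if (is.null(brain_semiaxes))
    brain_semiaxes <- c(0.42, 0.38, 0.40) * grid_dims
  structure(
    list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
         brain_semiaxes = brain_semiaxes, texture_sd = texture_sd,
         texture_fwhm_mm = texture_fwhm_mm, noise_sd = noise_sd,
         target_fraction = target_fraction, effect_size = effect_size,
         n_per_group = as.integer(n_per_group), regions = regions,
         smooth_noise_fwhm_mm = smooth_noise_fwhm_mm, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Ellipsoid indicator on the grid, centered mid-grid.
ellipsoid_mask_ <- function(dims, semiaxes, center = (dims + 1) / 2) {
  ix <- seq_len(dims[1]); iy <- seq_len(dims[2]); iz <- seq_len(dims[3])
  dx2 <- ((ix - center[1]) / semiaxes[1])^2
  dy2 <- ((iy - center[2]) / semiaxes[2])^2
  dz2 <- ((iz - center[3]) / semiaxes[3])^2
  array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1, dims)
}

sphere_mask_ <- function(dims, center, radius) {
  ellipsoid_mask_(dims, rep(max(radius, 1e-9), 3), center)
}

# Default effect support: two spheres at fixed fractional offsets inside
# the brain, radii chosen so their joint volume hits the target fraction.
default_regions_ <- function(spec, n_brain) {
  target_vox <- spec$target_fraction * n_brain
  c0 <- (spec$grid_dims + 1) / 2
  a <- spec$brain_semiaxes
  r1 <- (3 / (4 * pi) * 0.7 * target_vox)^(1 / 3)
  r2 <- (3 / (4 * pi) * 0.3 * target_vox)^(1 / 3)
  list(list(center = c0 + c(0.45, 0.30, 0.10) * a * c(1, 1, 1) * 0.9, radius = r1),
       list(center = c0 - c(0.40, 0.25, -0.20) * a * 0.9, radius = r2))
}

#' Ground-truth effect-region mask of a phantom spec
#'
#' Voxelizes the union of the effect spheres; regions reaching outside the
#' brain ellipsoid are an error. If the achieved fraction of brain voxels
#' deviates from `target_fraction` by more than 20% (relative), a warning
#' is raised.
#'
#' @param spec A [phantom_spec()].
#' @return A [binary_mask()] with provenance `"region_truth"`.
#' @export
region_mask <- function(spec) {
  brain <- ellipsoid_mask_(spec$grid_dims, spec$brain_semiaxes)
  regions <- spec$regions
  if (is.null(regions)) regions <- default_regions_(spec, sum(brain))
  g <- array(FALSE, spec$grid_dims)
  for (r in regions)
    g <- g | sphere_mask_(spec$grid_dims, r$center, r$radius)
  if (!all(!g | brain))
    abort("spec error: effect regions must lie inside the brain.",
          class = "tmasking_spec_error")
  frac <- sum(g) / sum(brain)
  if (abs(frac - spec$target_fraction) > 0.2 * spec$target_fraction)
    warn(sprintf(
      "achieved region fraction %.3f deviates >20%% from target %.3f",
      frac, spec$target_fraction))
  binary_mask(g, "region_truth", params = list(fraction = frac))
}

#' Generate a synthetic phantom cohort
#'
#' Builds one shared template (base tissue intensity 1 plus a smoothed
#' Gaussian random texture field inside the brain ellipsoid, 0 outside),
#' then per subject adds an i.i.d. Normal(0, `noise_sd`) field; group-1
#' subjects additionally receive a uniform decrement of
#' `effect_size * noise_sd` within the effect regions, so the per-voxel
#' in-region Cohen's d equals `effect_size` exactly in expectation. Groups
#' are balanced and everything is reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` ([volume_stack()]), `brain_mask`,
#'   `region_mask` (both [binary_mask()]), and `spec`.
#' @export
generate_cohort <- function(spec) {
  dims <- spec$grid_dims
  vs <- rep(spec$voxel_size_mm, 3)
  brain <- ellipsoid_mask_(dims, spec$brain_semiaxes)
  region <- suppressWarnings(region_mask(spec))
  with_seed_(spec$seed, {
    texture <- array(rnorm(prod(dims), 0, 1), dims)
    texture <- smooth_volume(texture, spec$texture_fwhm_mm, vs)
    # renormalize after smoothing so the texture sd is as requested
    texture <- texture / max(sd(as.vector(texture)), 1e-12) * spec$texture_sd
    template <- (1 + texture) * brain
    n <- spec$n_per_group
    labels <- rep(c(0L, 1L), each = n)
    shift <- spec$effect_size * spec$noise_sd * region$grid
    vols <- lapply(seq_len(2L * n), function(i) {
      noise <- array(rnorm(prod(dims), 0, spec$noise_sd), dims)
      if (spec$smooth_noise_fwhm_mm > 0) {
        noise <- smooth_volume(noise, spec$smooth_noise_fwhm_mm, vs)
        noise <- noise / max(sd(as.vector(noise)), 1e-12) * spec$noise_sd
      }
      v <- template + noise
      if (labels[i] == 1L) v <- v - shift
      v
    })
    stack <- volume_stack(vols, labels,
                          sprintf("sub-%03d", seq_len(2L * n)), vs)
  })
  list(stack = stack, brain_mask = binary_mask(brain, "brain"),
       region_mask = region, spec = spec)
}

#' Write a phantom cohort in the standard on-disk layout
#'
#' One NIfTI per subject (named by subject id), `participants.tsv`,
#' `brain_mask.nii.gz`, `region_truth.nii.gz` and `spec.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- cohort$stack
  for (i in seq_along(st$volumes))
    write_volume(st$volumes[[i]], st$affine,
                 file.path(dir, paste0(st$subject_ids[i], ".nii.gz")))
  utils::write.table(
    data.frame(subject_id = st$subject_ids, label = st$labels),
    file.path(dir, "participants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_mask(cohort$brain_mask, st$affine, file.path(dir, "brain_mask.nii.gz"))
  write_mask(cohort$region_mask, st$affine, file.path(dir, "region_truth.nii.gz"))
  sp <- cohort$spec
  sp$regions <- NULL
  jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
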