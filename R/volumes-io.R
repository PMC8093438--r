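#' Assemble a cohort of co-registered 3D volumes
#'
#' A `volume_stack` is an ordered cohort of same-grid 3D intensity volumes
#' (one per subject) together with per-subject binary labels, subject ids,
#' the voxel sizes in millimetres and a shared 4x4 grid-to-world affine.
#' All downstream operations (voxel-wise t-maps, masking, classification)
#' assume the volumes are spatially aligned on this common grid.
#'
#' @param volumes List of numeric 3D arrays, all of identical dimensions.
#' @param labels Integer/numeric vector of 0/1 class labels, one per volume.
#' @param subject_ids Character vector of unique subject identifiers;
#'   defaults to `sub-001`, `sub-002`, ...
#' @param voxel_sizes_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 grid-to-world matrix; defaults to a diagonal scaling by
#'   `voxel_sizes_mm`. Carried through unchanged by every operation.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(volumes, labels, subject_ids = NULL,
                         voxel_sizes_mm = c(1, 1, 1), affine = NULL) {
  if (!is.list(volumes) || length(volumes) == 0L)
    abort("`volumes` must be a non-empty list of 3D arrays.", class = "tmasking_error")
  dims <- dim(volumes[[1]])
  if (length(dims) != 3L)
    abort("volumes must be 3D arrays.", class = "tmasking_error")
  for (v in volumes)
    if (!identical(dim(v), dims))
      abort("inconsistent grid: all volumes must share one shape.",
            class = "tmasking_grid_error")
  labels <- as.integer(labels)
  if (length(labels) != length(volumes) || !all(labels %in% c(0L, 1L)))
    abort("label error: need one label in {0,1} per volume.",
          class = "tmasking_label_error")
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub-%03d", seq_along(volumes))
  if (anyDuplicated(subject_ids) || length(subject_ids) != length(volumes))
    abort("participants table error: subject ids must be unique, one per volume.",
          class = "tmasking_participants_error")
  voxel_sizes_mm <- as.numeric(voxel_sizes_mm)
  stopifnot(length(voxel_sizes_mm) == 3L, all(voxel_sizes_mm > 0))
  if (is.null(affine)) affine <- diag(c(voxel_sizes_mm, 1))
  structure(
    list(volumes = volumes, labels = labels, subject_ids = as.character(subject_ids),
         voxel_sizes_mm = voxel_sizes_mm, affine = affine, dims = dims),
    class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("<volume_stack> %d subjects on a %s grid (%s mm voxels)\n",
              length(x$volumes), paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_sizes_mm, 3), collapse = "x")))
  cat(sprintf("  labels: %d zeros, %d ones\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' @export
length.volume_stack <- function(x) length(x$volumes)

#' Subset a volume stack by subject
#'
#' @param stack A [volume_stack()].
#' @param i Integer or logical index over subjects.
#' @return A `volume_stack` with the selected subjects, in index order.
#' @export
stack_subset <- function(stack, i) {
  volume_stack(stack$volumes[i], stack$labels[i], stack$subject_ids[i],
               stack$voxel_sizes_mm, stack$affine)
}

#' Construct a binary voxel mask
#'
#' Binary masks represent the brain support, thresholded t-masks, their
#' perturbed variants, random feature-selection masks, and ground-truth
#' effect regions of synthetic phantoms. Values are strictly 0/1.
#'
#' @param grid 3D array of 0/1 values (logical or numeric).
#' @param provenance One of `"brain"`, `"tmask"`, `"tmask_noise"`,
#'   `"tmask_bernoulli"`, `"random"`, `"region_truth"`.
#' @param params Named list of parameters that produced the mask
#'   (e.g. threshold, knockout probability).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, provenance = "brain", params = list()) {
  provenance <- match.arg(provenance, c("brain", "tmask", "tmask_noise",
                                        "tmask_bernoulli", "random", "region_truth"))
  if (length(dim(grid)) != 3L)
    abort("mask grid must be a 3D array.", class = "tmasking_error")
  g <- array(as.integer(grid != 0), dim = dim(grid))
  if (!all(grid %in% c(0, 1, TRUE, FALSE)))
    abort("mask values must be strictly in {0,1}.", class = "tmasking_mask_error")
  structure(list(grid = g, provenance = provenance, params = params),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %d of %d voxels active\n",
              x$provenance, sum(x$grid), length(x$grid)))
  invisible(x)
}

#' Number of active voxels in a mask
#' @param mask A [binary_mask()].
#' @return Integer count of 1-valued voxels.
#' @export
mask_size <- function(mask) sum(mask$grid)

#' Read a cohort of NIfTI volumes with a participants table
#'
#' Reads one NIfTI volume per subject, validates that all volumes share one
#' grid and affine, and pairs them with a participants table carrying the
#' binary labels. Volumes are matched to table rows by subject id, taken
#' from the file basename with NIfTI extensions stripped.
#'
#' @param volume_paths Character vector of `.nii`/`.nii.gz` file paths.
#' @param participants Path to a TSV file with columns `subject_id` and
#'   `label`, or a data frame with those columns.
#' @param brain_mask Optional path to a NIfTI brain mask on the same grid.
#' @return A list with elements `stack` (a [volume_stack()]) and
#'   `brain_mask` (a [binary_mask()] or `NULL`).
#' @export
read_cohort <- function(volume_paths, participants, brain_mask = NULL) {
  if (is.character(participants)) {
    participants <- utils::read.delim(participants, sep = "\t",
                                      colClasses = c(subject_id = "character"))
  }
  if (!all(c("subject_id", "label") %in% names(participants)))
    abort("participants table error: need columns `subject_id` and `label`.",
          class = "tmasking_participants_error")
  if (anyDuplicated(participants$subject_id))
    abort("participants table error: duplicate subject ids.",
          class = "tmasking_participants_error")
  if (!all(participants$label %in% c(0, 1)))
    abort("label error: labels must be 0 or 1.", class = "tmasking_label_error")
  ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  if (!setequal(ids, participants$subject_id) ||
      length(ids) != nrow(participants))
    abort("participants table error: file names and subject ids do not match one-to-one.",
          class = "tmasking_participants_error")
  volume_paths <- volume_paths[match(participants$subject_id, ids)]
  vols <- lapply(volume_paths, read_volume)
  dims <- dim(vols[[1]]$grid)
  aff <- vols[[1]]$affine
  for (v in vols) {
    if (!identical(dim(v$grid), dims) || max(abs(v$affine - aff)) > 1e-4)
      abort("inconsistent grid: volumes differ in shape or affine.",
            class = "tmasking_grid_error")
  }
  stack <- volume_stack(lapply(vols, `[[`, "grid"), participants$label,
                        participants$subject_id, vols[[1]]$voxel_sizes_mm, aff)
  bm <- NULL
  if (!is.null(brain_mask)) {
    m <- read_volume(brain_mask)
    if (!identical(dim(m$grid), dims))
      abort("inconsistent grid: brain mask shape differs from volumes.",
            class = "tmasking_grid_error")
    bm <- binary_mask(m$grid != 0, "brain")
  }
  list(stack = stack, brain_mask = bm)
}

#' Read a single NIfTI volume
#' @param path NIfTI file path.
#' @return List with `grid` (3D array), `affine` (4x4), `voxel_sizes_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vs <- abs(RNifti::pixdim(img))[1:3]
  list(grid = array(as.numeric(img), dim = dim(img)), affine = aff,
       voxel_sizes_mm = vs)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float32, masks as unsigned 8-bit. The affine is
#' written into both the qform and sform. `write_mask()` rejects grids with
#' values outside \{0,1\} before writing; mask round trips are bit-exact,
#' volume round trips are exact to float32 precision.
#'
#' @param grid Numeric 3D array (for `write_volume`).
#' @param affine 4x4 grid-to-world matrix.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param mask A [binary_mask()] (for `write_mask`).
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(grid), dim = dim(grid)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, affine, path) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask, "brain")
  img <- RNifti::asNifti(array(as.integer(mask$grid), dim = dim(mask$grid)))
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Per-volume intensity normalization
#'
#' Rescales each volume independently to zero mean and unit standard
#' deviation, the standard intensity normalization applied before feeding
#' volumes to a gradient-trained classifier. The standard deviation uses
#' the population convention (divide by the number of support voxels).
#' When a mask is supplied, the statistics are computed over mask voxels
#' only and voxels outside the mask are set to 0; otherwise the whole
#' volume is the support.
#'
#' @param stack A [volume_stack()].
#' @param within_mask Optional [binary_mask()] giving the normalization
#'   support (e.g. a brain mask).
#' @return A `volume_stack` with normalized volumes.
#' @export
znormalize <- function(stack, within_mask = NULL) {
  sup <- if (is.null(within_mask)) NULL else which(within_mask$grid != 0)
  vols <- lapply(stack$volumes, function(v) {
    x <- if (is.null(sup)) as.vector(v) else as.vector(v)[sup]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))
    if (sdev < 1e-12)
      abort("degenerate volume: zero intensity variance over the support.",
            class = "tmasking_degenerate_error")
    if (is.null(sup)) {
      array((v - mu) / sdev, dim = dim(v))
    } else {
      out <- array(0, dim = dim(v))
      out[sup] <- (as.vector(v)[sup] - mu) / sdev
      out
    }
  })
  volume_stack(vols, stack$labels, stack$subject_ids, stack$voxel_sizes_mm,
               stack$affine)
}
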