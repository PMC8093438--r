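# Small in-code fixtures shared across test files.

# Random-noise cohort on a small grid, optionally with a group mean shift
# restricted to a fixed corner region (so the discriminative voxels are
# known exactly).
tiny_cohort <- function(n_per_group = 10, dims = c(8, 8, 8), shift = 0,
                        seed = 1) {
  withr::with_seed(seed, {
    region <- array(FALSE, dims)
    region[1:3, 1:3, 1:3] <- TRUE
    labels <- rep(c(0L, 1L), each = n_per_group)
    vols <- lapply(labels, function(l) {
      v <- array(rnorm(prod(dims)), dims)
      if (l == 1L) v[region] <- v[region] + shift
      v
    })
    list(stack = volume_stack(vols, labels),
         region = binary_mask(region, "region_truth"),
         brain = binary_mask(array(TRUE, dims), "brain"))
  })
}

# Brute-force per-voxel absolute equal-variance two-sample t, via t.test().
oracle_tmap <- function(stack) {
  g0 <- stack$labels == 0L
  X <- sapply(stack$volumes, as.vector)
  apply(X, 1L, function(r)
    abs(t.test(r[g0], r[!g0], var.equal = TRUE)$statistic))
}

# A tmap object with prescribed statistic values and support, for tests
# that exercise thresholding and perturbation in isolation.
fake_tmap <- function(grid, support = NULL) {
  structure(list(grid = grid, mode = "standard", fwhm_mm = 0,
                 n0 = 2L, n1 = 2L, support = support,
                 voxel_sizes_mm = c(1, 1, 1), affine = diag(4)),
            class = "tmap")
}

fake_heat <- function(grid) {
  structure(list(grid = grid, layer = "concat", target = "loss"),
            class = "heat_map")
}
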