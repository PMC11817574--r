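# Compact phantom configurations used across the test files.

# Full-size default geometry but noiseless and unsmoothed: closed-form
# recovery should be exact away from blended boundaries.
noiseless_spec <- function(...) {
  phantom_spec(rician_sigma = 0, pet_noise_sigma = 0,
               smoothing_fwhm_mm = 0, boundary_blend_vox = 0, ...)
}

# Smaller grid for replicate Monte-Carlo runs; same spacing and lesion
# geometry, so per-lesion voxel counts are unchanged.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 20L),
               prostate_ellipsoid = list(center = c(41.6, 41.6, 31.2),
                                         semi_axes = c(22, 20, 16)),
               ...)
}

# A deterministic SUV grid + full-coverage manual ROI for mask algebra.
ramp_suv <- function(d = c(3L, 3L, 1L), values = seq_len(prod(d))) {
  voxel_grid(array(as.numeric(values), d), c(1, 1, 1), "suv")
}

full_roi <- function(d = c(3L, 3L, 1L), zone = "PZ") {
  roi_mask(array(TRUE, d), zone = zone)
}

# Reference PET method only: cuts subject generation time when the bias
# emulator is not under test.
ct_only <- function() list(CT_reference = bias_spec("CT_reference"))
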