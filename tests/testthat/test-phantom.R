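test_that("phantom spec validates geometry and ranges", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(lesion_ellipsoid = list(center = c(200, 200, 90),
                                                    semi_axes = c(7, 6, 5))),
               "inside the prostate")
  expect_error(phantom_spec(lesion_adc_range = c(1.1, 0.6)), "low < high")
  expect_error(phantom_spec(coupling_rho = -1.5), "coupling_rho")
  expect_error(phantom_spec(rician_sigma = -0.1), "nonnegative")
  expect_error(phantom_spec(b0_signal_au = 0), "positive")
})

test_that("subject generation is deterministic and rejects out-of-range lesions", {
  spec <- small_spec()
  s1 <- generate_subject(spec, 0.8, 10, seed = 5, bias_specs = ct_only())
  s2 <- generate_subject(spec, 0.8, 10, seed = 5, bias_specs = ct_only())
  expect_identical(s1, s2)
  s3 <- generate_subject(spec, 0.8, 10, seed = 6, bias_specs = ct_only())
  expect_false(identical(s1$dwi_b0$values, s3$dwi_b0$values))

  expect_error(generate_subject(spec, 0.2, 10, seed = 1), "lesion_adc")
  expect_error(generate_subject(spec, 0.8, 30, seed = 1), "lesion_suv")
})

test_that("noiseless phantom inverts exactly: ADC and SUV recovered in the ROI", {
  spec <- noiseless_spec()
  s <- generate_subject(spec, 0.75, 12.5, seed = 9, bias_specs = ct_only())
  adc <- compute_adc(s$dwi_b0, s$dwi_b800, 800)
  expect_lt(max(abs(extract_values(adc, s$roi) - 0.75)) / 0.75, 1e-10)
  suv <- compute_suv(s$pet_by_method$CT_reference, s$dose)
  expect_lt(max(abs(extract_values(suv, s$roi) - 12.5)) / 12.5, 1e-10)
  # noiseless decay law holds exactly: S(b800)/S(b0) = exp(-0.8 * ADC)
  inside <- s$dwi_b0$values > 0
  expect_equal(s$dwi_b800$values[inside] / s$dwi_b0$values[inside],
               exp(-0.8 * s$true_adc$values[inside]), tolerance = 1e-12)
})

test_that("smoothed noiseless phantom recovers a programmed SUV_mean of 16.75 within 15%", {
  # partial volume from the 3 mm reconstruction filter biases the lesion
  # mean downward at this lesion size; the bound is the documented
  # smoothing-induced tolerance
  spec <- phantom_spec(rician_sigma = 0, pet_noise_sigma = 0,
                       boundary_blend_vox = 0)
  s <- generate_subject(spec, 0.8, 16.75, seed = 9, bias_specs = ct_only())
  suv <- compute_suv(s$pet_by_method$CT_reference, s$dose)
  m60 <- threshold_mask(suv, s$roi, 60)
  f <- histogram_features(extract_values(suv, m60), "SUV")
  expect_lt(abs(f$mean - 16.75) / 16.75, 0.15)
  expect_lt(abs(roi_suv_max(suv, s$roi) - 16.75) / 16.75, 0.05)
})

test_that("Rician noise model: identity at zero, Rayleigh mean at zero signal, nonnegative", {
  z <- voxel_grid(array(0, c(40, 40, 25)), c(1, 1, 1), "signal_au")
  expect_identical(add_rician_noise(z, 0, seed = 1), z)

  # s = 0: magnitude is Rayleigh with mean sigma * sqrt(pi/2)
  noisy <- add_rician_noise(z, 2, seed = 17)
  expect_true(all(noisy$values >= 0))
  expect_equal(mean(noisy$values), 2 * sqrt(pi / 2), tolerance = 0.02)

  # determinism
  expect_identical(add_rician_noise(z, 2, seed = 17), noisy)
})

test_that("lesion truth pairs follow the programmed rank coupling", {
  spec <- small_spec()
  # antimonotone limit: sample Spearman exactly -1
  tr <- sample_lesion_truth(spec, 27, -1, seed = 2)
  expect_equal(stats::cor(tr$lesion_adc, tr$lesion_suv, method = "spearman"),
               -1)
  # marginals stay inside the programmed ranges
  expect_true(all(tr$lesion_adc >= spec$lesion_adc_range[1] &
                    tr$lesion_adc <= spec$lesion_adc_range[2]))
  expect_true(all(tr$lesion_suv >= spec$lesion_suv_range[1] &
                    tr$lesion_suv <= spec$lesion_suv_range[2]))

  # coupling fidelity: mean sample rho within 0.03 of target, 400 cohorts
  targets <- c(0, -0.3, -0.5, -0.8)
  for (k in seq_along(targets)) {
    rhos <- vapply(1:400, function(i) {
      p <- sample_lesion_truth(spec, 27, targets[k], seed = k * 100000 + i)
      stats::cor(p$lesion_adc, p$lesion_suv, method = "spearman")
    }, numeric(1))
    expect_lt(abs(mean(rhos) - targets[k]), 0.03)
  }
  # null sd close to the large-sample 1/sqrt(n-1)
  rhos0 <- vapply(1:200, function(i) {
    p <- sample_lesion_truth(spec, 27, 0, seed = i)
    stats::cor(p$lesion_adc, p$lesion_suv, method = "spearman")
  }, numeric(1))
  expect_equal(stats::sd(rhos0), 1 / sqrt(26), tolerance = 0.2)
})

test_that("cohort has the requested zone composition and reproducible subjects", {
  coh <- generate_cohort(small_spec(), n_subjects = 6, n_pz = 4, seed = 12,
                         bias_specs = ct_only())
  tr <- cohort_truth(coh)
  expect_identical(nrow(tr), 6L)
  expect_identical(sum(tr$zone == "PZ"), 4L)
  zones <- vapply(coh, function(s) s$roi$zone, "")
  expect_identical(zones, tr$zone)
  expect_error(generate_cohort(small_spec(), n_subjects = 2, seed = 1),
               "at least 3")
  expect_error(generate_cohort(small_spec(), n_subjects = 5, n_pz = 9,
                               seed = 1), "n_pz")

  # a single subject can be regenerated from the derived per-subject seed
  spec_i <- small_spec()
  spec_i$lesion_zone <- tr$zone[3]
  spec_i$lesion_ellipsoid <- petadc:::lesion_ellipsoid_for_zone(
    spec_i$prostate_ellipsoid, tr$zone[3])
  s3 <- generate_subject(spec_i, tr$lesion_adc[3], tr$lesion_suv[3],
                         seed = (12L + 7919L * 3L) %% 2147483000L,
                         bias_specs = ct_only(), subject_id = "S03")
  expect_identical(s3, coh[[3]])
})

test_that("bias emulator: identity at amplitude 0, exact field statistics, monotone error", {
  spec <- small_spec()
  s <- generate_subject(spec, 0.8, 10, seed = 30, bias_specs = ct_only())
  ref <- s$pet_by_method$CT_reference

  b0 <- bias_spec("MRI_like", 0)
  expect_identical(emulate_ac_method(ref, b0, seed = 1), ref)

  b <- bias_spec("MRI_like", 0.05)
  out <- emulate_ac_method(ref, b, seed = 1)
  f <- petadc:::bias_field(dim(ref$values), ref$spacing_mm, 0.05,
                           b$bias_field_correlation_length_mm,
                           1 + b$seed_offset)
  expect_equal(out$values, ref$values * (1 + f), tolerance = 1e-12)
  # standardized field: zero mean, sd = amplitude (exact by construction)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(stats::sd(f), 0.05, tolerance = 1e-12)
  # near-Gaussian field: E|f| = amplitude * sqrt(2/pi)
  expect_equal(mean(abs(f)), 0.05 * sqrt(2 / pi), tolerance = 0.01)

  # avg.RAE monotone nondecreasing in amplitude
  body <- ref$values > 0
  raes <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(a) {
    if (a == 0) return(0)
    o <- emulate_ac_method(ref, bias_spec("MRI_like", a), seed = 1)
    as.numeric(avg_rae(o$values[body], ref$values[body]))
  }, numeric(1))
  expect_true(all(diff(raes) >= 0))
  expect_error(bias_spec("CT_reference", 0.1), "amplitude 0")
})

test_that("PET volumes are nonnegative and grids congruent across modalities", {
  coh <- generate_cohort(small_spec(), n_subjects = 3, n_pz = 2, seed = 44)
  for (s in coh) {
    for (m in names(s$pet_by_method)) {
      expect_true(all(s$pet_by_method[[m]]$values >= 0))
      expect_identical(dim(s$pet_by_method[[m]]$values),
                       dim(s$dwi_b0$values))
    }
    expect_true(any(s$roi$mask))
    expect_true(all(s$dwi_b0$values >= 0))
  }
})
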