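# Independent central-moment oracle: the definitions written out directly
# from raw power sums, no shared code with the implementation.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d * d) / n
  m3 <- sum(d * d * d) / n
  m4 <- sum(d * d * d * d) / n
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

test_that("hand-computed moment examples are reproduced", {
  # symmetric set: skewness exactly 0
  fs <- histogram_features(c(1, 2, 2, 3), "SUV")
  expect_equal(fs$skewness, 0, tolerance = 1e-14)

  # two-point symmetric {0,0,1,1}: mean 0.5, median 0.5, excess kurtosis -2
  fs2 <- histogram_features(c(0, 0, 1, 1), "SUV")
  expect_equal(fs2$mean, 0.5)
  expect_equal(fs2$median, 0.5)
  expect_equal(fs2$kurtosis, -2, tolerance = 1e-14)
  expect_equal(fs2$skewness, 0, tolerance = 1e-14)
  expect_identical(fs2$min, 0)
  expect_identical(fs2$max, 1)

  # even-length median is the midpoint of the central order statistics
  expect_equal(histogram_features(c(1, 2, 10, 20), "ADC")$median, 6)
})

test_that("skewness/kurtosis match the independent oracle on 1000 random sets", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(4:500, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), round(runif(n, 0, 5), 1))  # incl. ties
    if (stats::var(x) == 0) next
    fs <- histogram_features(x, "SUV")
    or <- oracle_moments(x)
    # shape statistics are O(1) scale-free quantities: absolute tolerance
    expect_true(abs(fs$skewness - or$skewness) <= 1e-12)
    expect_true(abs(fs$kurtosis - or$kurtosis) <= 1e-12)
    expect_equal(fs$mean, mean(x), tolerance = 1e-12)
    expect_identical(fs$n_voxels, n)
  }
})

test_that("population convention agrees with e1071 type-1 estimators", {
  set.seed(12)
  x <- rgamma(200, 2)
  fs <- histogram_features(x, "ADC")
  expect_equal(fs$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(fs$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})

test_that("location-scale behaviour: moments equivariant, shape invariant", {
  set.seed(13)
  x <- rlnorm(60)
  a <- 2.5; b <- -1.2
  f0 <- histogram_features(x, "SUV")
  f1 <- histogram_features(a * x + b, "SUV")
  expect_equal(f1$mean, a * f0$mean + b, tolerance = 1e-10)
  expect_equal(f1$max, a * f0$max + b, tolerance = 1e-10)
  expect_equal(f1$min, a * f0$min + b, tolerance = 1e-10)
  expect_equal(f1$median, a * f0$median + b, tolerance = 1e-10)
  expect_equal(f1$skewness, f0$skewness, tolerance = 1e-10)
  expect_equal(f1$kurtosis, f0$kurtosis, tolerance = 1e-10)
})

test_that("negative excess kurtosis is representable on platykurtic sets", {
  # uniform-ish values: platykurtic, so Fisher excess must go negative
  fs <- histogram_features(seq(0, 1, length.out = 50), "SUV")
  expect_lt(fs$kurtosis, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(histogram_features(c(1, 2, 3), "SUV"), "at least 4")
  expect_error(histogram_features(rep(2, 10), "SUV"), "constant region")
  expect_error(histogram_features(c(1, 2, NA, 4), "SUV"), "finite")
})

test_that("cohort feature table has one ADC and one SUV row per subject", {
  coh <- generate_cohort(small_spec(), n_subjects = 5, n_pz = 3, seed = 21,
                         bias_specs = ct_only())
  ft <- cohort_feature_table(coh, "CT_reference", 0)
  expect_identical(nrow(ft), 10L)
  expect_identical(sort(unique(ft$modality)), c("ADC", "SUV"))
  expect_setequal(unique(ft$subject_id), cohort_truth(coh)$subject_id)
  expect_true(all(feature_names() %in% names(ft)))
  # invariant min <= median <= max and min <= mean <= max per row
  expect_true(all(ft$min <= ft$median & ft$median <= ft$max))
  expect_true(all(ft$min <= ft$mean & ft$mean <= ft$max))
  expect_identical(nrow(attr(ft, "exclusions")), 0L)
})

test_that("max grows and min shrinks as the threshold decreases", {
  coh <- generate_cohort(small_spec(), n_subjects = 3, n_pz = 2, seed = 22,
                         bias_specs = ct_only())
  tabs <- lapply(c(60L, 30L, 10L), function(p)
    cohort_feature_table(coh, "CT_reference", p))
  for (s in unique(tabs[[1]]$subject_id)) {
    for (mod in c("ADC", "SUV")) {
      vals <- lapply(tabs, function(t) t[t$subject_id == s & t$modality == mod, ])
      # going 60 -> 30 -> 10: mask grows
      expect_true(vals[[1]]$max <= vals[[2]]$max)
      expect_true(vals[[2]]$max <= vals[[3]]$max)
      expect_true(vals[[1]]$min >= vals[[2]]$min)
      expect_true(vals[[2]]$min >= vals[[3]]$min)
    }
  }
})

test_that("a corrupted subject is excluded with a logged reason", {
  coh <- generate_cohort(small_spec(), n_subjects = 4, n_pz = 2, seed = 23,
                         bias_specs = ct_only())
  coh[[2]]$pet_by_method <- list()   # no PET volumes at all
  ft <- cohort_feature_table(coh, "CT_reference", 0)
  expect_identical(length(unique(ft$subject_id)), 3L)
  excl <- attr(ft, "exclusions")
  expect_identical(nrow(excl), 1L)
  expect_match(excl$reason, "CT_reference")
  # fewer than 3 survivors is fatal
  coh3 <- coh[1:3]
  coh3[[1]]$pet_by_method <- list()
  expect_error(cohort_feature_table(coh3, "CT_reference", 0), "< 3")
})
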