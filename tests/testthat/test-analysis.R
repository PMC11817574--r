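# Brute-force rank correlation oracle: average ranks computed by counting,
# then the Pearson formula written out directly.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      less <- sum(v < v[i]); equal <- sum(v == v[i])
      less + (equal + 1) / 2
    })
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

test_that("spearman_rho hits the monotone limits and matches the oracle", {
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  x <- c(0.3, 1.1, 2.2, 5.0, 9.7)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)

  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- round(runif(n, 0, 5), 1)   # ties likely
    y <- round(rnorm(n), 1)
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("spearman p-values: t-approximation matches cor.test, small-n is permutation-exact", {
  set.seed(32)
  x <- rnorm(20); y <- rnorm(20)
  ours <- spearman_rho(x, y)
  expect_identical(ours$method, "t-approximation")
  ref <- stats::cor.test(x, y, method = "spearman")
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)

  # n = 5, no ties: enumerate the permutation null by hand and compare
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 5, 3)
  ours5 <- spearman_rho(x5, y5)
  expect_identical(ours5$method, "exact permutation")
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  null_rho <- apply(perms, 1, function(idx) stats::cor(rank(x5), rank(y5)[idx]))
  p_manual <- mean(abs(null_rho) >= abs(ours5$rho) - 1e-12)
  expect_equal(ours5$p_value, p_manual, tolerance = 1e-12)
})

test_that("mann_whitney matches exact enumeration", {
  # fully separated samples: U = 0, exact two-sided p = 2 / C(6,3) = 0.1
  expect_equal(mann_whitney(c(1, 2, 3), c(10, 11, 12)), 0.1,
               tolerance = 1e-12)

  # identical tied samples: maximal p
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)

  # all 4-vs-4 splits of 8 distinct values against a permutation oracle
  vals <- c(0.4, 1.2, 2.7, 3.1, 5.8, 6.6, 7.9, 9.3)
  splits <- utils::combn(8, 4)
  for (j in seq_len(ncol(splits))) {
    a <- vals[splits[, j]]; b <- vals[-splits[, j]]
    u_obs <- sum(outer(a, b, ">"))
    # null distribution of U over all C(8,4) assignments
    u_null <- apply(splits, 2, function(idx)
      sum(outer(vals[idx], vals[-idx], ">")))
    # two-sided p: tail probability of |U - n1 n2 / 2|
    p_oracle <- mean(abs(u_null - 8) >= abs(u_obs - 8))
    expect_equal(mann_whitney(a, b), p_oracle, tolerance = 1e-12)
  }
})

test_that("avg_rae implements the printed formula and its identities", {
  expect_equal(as.numeric(avg_rae(c(2, 2), c(1, 2))), 50)
  x <- c(3.2, 0.5, 7.7, 1.1)
  expect_equal(as.numeric(avg_rae(x, x)), 0)
  expect_equal(as.numeric(avg_rae(1.1 * x, x)), 10, tolerance = 1e-10)
  for (cc in c(0.01, 0.1, 0.5)) {
    expect_equal(as.numeric(avg_rae((1 + cc) * x, x)), 100 * cc,
                 tolerance = 1e-9)
    expect_equal(as.numeric(avg_rae((1 - cc) * x, x)), 100 * cc,
                 tolerance = 1e-9)
  }
  # near-zero reference voxels are excluded and counted
  r <- avg_rae(c(1, 2, 3), c(0, 2, 3), eps = 1e-6)
  expect_identical(attr(r, "n_excluded"), 1L)
  expect_equal(as.numeric(r), 0)
  expect_error(avg_rae(c(1, 2), c(0, 0)), "exclusion floor")
})

test_that("correlation grid propagates a perfect antimonotone truth", {
  # no noise; smoothing and boundary blending stay on (deterministic and
  # identical for every same-geometry subject, so subject ranks are
  # preserved exactly while within-ROI variance stays positive); a single
  # zone keeps the geometry identical across subjects
  spec <- small_spec(rician_sigma = 0, pet_noise_sigma = 0)
  coh <- generate_cohort(spec, n_subjects = 8, n_pz = 8, coupling_rho = -1,
                         seed = 33, bias_specs = ct_only())
  ft <- cohort_feature_table(coh, "CT_reference", 0)
  g <- correlation_grid(ft)
  expect_equal(g$rho["mean", "mean"], -1)
  expect_identical(g$n, 8L)
  td <- tidy(g)
  expect_identical(nrow(td), 36L)
  expect_true(all(abs(td$rho) <= 1, na.rm = TRUE))
  gl <- glance(g)
  expect_identical(gl$n, 8L)
})

test_that("a degenerate feature column yields NA cells, not zeros", {
  coh <- generate_cohort(small_spec(), n_subjects = 5, n_pz = 3, seed = 34,
                         bias_specs = ct_only())
  ft <- cohort_feature_table(coh, "CT_reference", 0)
  ft$kurtosis[ft$modality == "SUV"] <- 7   # constant column
  g <- correlation_grid(ft)
  expect_true(all(is.na(g$rho[, "kurtosis"])))
  expect_false(anyNA(g$rho[, "mean"]))
})

test_that("correlation grids are invariant under monotone feature transforms", {
  coh <- generate_cohort(small_spec(), n_subjects = 6, n_pz = 4, seed = 35,
                         bias_specs = ct_only())
  ft <- cohort_feature_table(coh, "CT_reference", 0)
  g0 <- correlation_grid(ft)
  ft2 <- ft
  ft2$mean <- exp(ft2$mean)              # strictly increasing
  ft2$kurtosis <- ft2$kurtosis^3         # strictly increasing (sign kept)
  g1 <- correlation_grid(ft2)
  expect_equal(g1$rho, g0$rho, tolerance = 1e-12)
})

test_that("identical methods give zero error and not-applicable tests", {
  coh <- generate_cohort(small_spec(), n_subjects = 4, n_pz = 2, seed = 36,
                         bias_specs = list(
                           CT_reference = bias_spec("CT_reference"),
                           MRI_like = bias_spec("MRI_like", 0),
                           DL_like = bias_spec("DL_like", 0)))
  rep <- feature_error_report(coh)
  expect_true(all(rep$errors$mean_rae == 0))
  expect_true(all(is.na(rep$tests$t_test_p)))
  expect_true(all(is.na(rep$tests$rank_test_p)))
})
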