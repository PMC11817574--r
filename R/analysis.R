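#' Spearman rank correlation with a two-sided p-value
#'
#' Ranks use average ranks for ties; rho is the Pearson correlation of the
#' ranks. The two-sided p-value uses the t-approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) for n >= 8 and exact enumeration
#' of all permutations of one rank vector for n < 8 (where the
#' approximation is poor and enumeration is cheap).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A list with `rho`, `p_value`, `n`, and `method` ("t-approximation"
#'   or "exact permutation").
#' @export
#' @examples
#' spearman_rho(1:3, c(3, 2, 1))$rho  # -1
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: ranks degenerate, rho undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 8L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  } else {
    perms <- permutations_of(n)
    rho_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# All permutations of 1..n as an (n!) x n matrix; only used for small n.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact p-value when the combined sample size is at most 12 and there are
#' no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y numeric samples, each of length >= 3.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) {
    stop("each sample needs at least 3 observations", call. = FALSE)
  }
  n <- length(x) + length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = (n <= 12L && !has_ties),
                       correct = TRUE, alternative = "two.sided")
  )
  unname(res$p.value)
}

#' Average relative absolute error (percent)
#'
#' avg.RAE = (1/N) * sum over ROI voxels of |Px - Pref| / |Pref| * 100,
#' comparing a reconstructed volume's values against the reference. Voxels
#' whose reference magnitude is at or below the floor `eps` are excluded
#' from the average and counted (attribute `n_excluded`); the relative
#' error is unstable there.
#'
#' @param px numeric vector of values under test.
#' @param pref numeric vector of reference values, same length.
#' @param eps exclusion floor on `|pref|` (default 1e-6).
#' @return avg.RAE in percent, with attribute `n_excluded`.
#' @export
#' @examples
#' avg_rae(c(2, 2), c(1, 2))  # 50
avg_rae <- function(px, pref, eps = 1e-6) {
  px <- as.numeric(px); pref <- as.numeric(pref)
  if (length(px) != length(pref) || length(px) < 1L) {
    stop("`px` and `pref` must have equal positive length", call. = FALSE)
  }
  keep <- abs(pref) > eps
  if (!any(keep)) {
    stop("all reference values at or below the exclusion floor", call. = FALSE)
  }
  out <- mean(abs(px[keep] - pref[keep]) / abs(pref[keep])) * 100
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Cross-subject Spearman correlation grid of ADC vs SUV features
#'
#' For one PET method and threshold level, correlates each ADC feature
#' against each SUV feature across subjects, producing a 6 x 6 grid of
#' Spearman's rho and per-cell two-sided p-values. Feature order is fixed:
#' mean, max, min, median, kurtosis, skewness (rows = ADC, columns = SUV).
#' A degenerate (constant) feature column leaves its cells `NA` (marked
#' missing, never silently zero). No multiple-testing correction is
#' applied across the 36 cells; p-values are nominal.
#'
#' @param feature_table tibble from [cohort_feature_table()] (long, one
#'   row per subject x modality).
#' @param method_label,threshold_pct select the rows to correlate; default
#'   taken from the table if it is homogeneous.
#' @return An object of class `correlation_grid` with fields `rho`
#'   (6 x 6 matrix), `p_values`, `n`, `method_label`, `threshold_pct`.
#'   Use [generics::tidy()] for a long tibble and `autoplot()` for a
#'   heatmap.
#' @export
correlation_grid <- function(feature_table, method_label = NULL,
                             threshold_pct = NULL) {
  ft <- feature_table
  if (!is.null(method_label)) ft <- ft[ft$method_label == method_label, ]
  if (!is.null(threshold_pct)) ft <- ft[ft$threshold_pct == threshold_pct, ]
  if (length(unique(ft$method_label)) != 1L ||
      length(unique(ft$threshold_pct)) != 1L) {
    stop("feature table mixes methods or thresholds; select one of each",
         call. = FALSE)
  }
  adc <- ft[ft$modality == "ADC", ]
  suv <- ft[ft$modality == "SUV", ]
  adc <- adc[order(adc$subject_id), ]
  suv <- suv[order(suv$subject_id), ]
  if (!identical(adc$subject_id, suv$subject_id)) {
    stop("ADC and SUV rows must cover the same subjects", call. = FALSE)
  }
  n <- nrow(adc)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  feats <- feature_names()
  rho <- p <- matrix(NA_real_, 6, 6, dimnames = list(ADC = feats, SUV = feats))
  for (i in feats) {
    for (j in feats) {
      cell <- tryCatch(spearman_rho(adc[[i]], suv[[j]]),
                       error = function(e) NULL)
      if (!is.null(cell)) {
        rho[i, j] <- cell$rho
        p[i, j] <- cell$p_value
      }
    }
  }
  structure(
    list(rho = rho, p_values = p, n = n,
         method_label = unique(ft$method_label),
         threshold_pct = unique(ft$threshold_pct)),
    class = "correlation_grid"
  )
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("<correlation_grid> %s, threshold %d%%, n = %d subjects\n",
              x$method_label, x$threshold_pct, x$n))
  print(round(x$rho, 2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation grid into a long tibble
#'
#' @param x a [correlation_grid()].
#' @param ... unused.
#' @return A tibble with columns `adc_feature`, `suv_feature`, `rho`,
#'   `p_value`, `method_label`, `threshold_pct`, `n`.
#' @method tidy correlation_grid
#' @export
tidy.correlation_grid <- function(x, ...) {
  feats <- feature_names()
  tidyr::expand_grid(adc_feature = feats, suv_feature = feats) |>
    dplyr::mutate(
      rho = x$rho[cbind(.data$adc_feature, .data$suv_feature)],
      p_value = x$p_values[cbind(.data$adc_feature, .data$suv_feature)],
      method_label = x$method_label,
      threshold_pct = x$threshold_pct,
      n = x$n
    )
}

#' One-row summary of a correlation grid
#'
#' Reports the strongest (largest |rho|) cell and the number of nominally
#' significant cells at alpha = 0.05 (uncorrected).
#'
#' @param x a [correlation_grid()].
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance correlation_grid
#' @export
glance.correlation_grid <- function(x, ...) {
  td <- tidy(x)
  td <- td[!is.na(td$rho), ]
  best <- td[which.max(abs(td$rho)), ]
  tibble::tibble(
    method_label = x$method_label,
    threshold_pct = x$threshold_pct,
    n = x$n,
    n_cells = nrow(td),
    n_significant_0.05 = sum(td$p_value < 0.05),
    strongest_adc_feature = best$adc_feature,
    strongest_suv_feature = best$suv_feature,
    strongest_rho = best$rho
  )
}

#' Per-feature attenuation-correction error report
#'
#' For every feature and every non-reference PET method, computes the
#' per-subject relative absolute error of the method's SUV feature value
#' against the reference method's value (the scalar N = 1 case of
#' [avg_rae()]), then summarises mean and standard deviation over the
#' cohort. Subjects whose reference feature magnitude is below
#' `min_abs_reference` are excluded from that feature's error with a
#' logged count (relative error is unstable near zero; this matters for
#' kurtosis, which sits near zero clinically). Methods are compared per
#' feature with a paired two-sided t-test on the per-subject errors and a
#' two-sided Mann-Whitney-Wilcoxon rank test as the nonparametric
#' companion; degenerate comparisons (all errors equal) are reported as
#' `NA`.
#'
#' @param cohort list of subjects.
#' @param reference_label reference PET method (default `"CT_reference"`).
#' @param other_labels methods to compare against the reference.
#' @param threshold_pct mask level at which features are computed
#'   (default 0, the manual ROI).
#' @param min_abs_reference exclusion floor on the reference feature
#'   magnitude (default 0.05).
#' @return An object of class `error_report` with `$errors` (tibble:
#'   feature, method_label, mean_rae, sd_rae, n_used, n_excluded),
#'   `$tests` (tibble: feature, method_a, method_b, t_test_p,
#'   rank_test_p), and `$per_subject` (tibble of per-subject errors).
#' @export
feature_error_report <- function(cohort, reference_label = "CT_reference",
                                 other_labels = c("MRI_like", "DL_like"),
                                 threshold_pct = 0L,
                                 min_abs_reference = 0.05) {
  tabs <- lapply(c(reference_label, other_labels), function(m) {
    ft <- cohort_feature_table(cohort, method_label = m,
                               threshold_pct = threshold_pct,
                               reference_label = reference_label)
    ft[ft$modality == "SUV", ]
  })
  names(tabs) <- c(reference_label, other_labels)
  ref <- tabs[[reference_label]]

  per_subject <- purrr::map_dfr(other_labels, function(m) {
    tab <- tabs[[m]]
    common <- intersect(ref$subject_id, tab$subject_id)
    r <- ref[match(common, ref$subject_id), ]
    t <- tab[match(common, tab$subject_id), ]
    purrr::map_dfr(feature_names(), function(f) {
      tibble::tibble(
        feature = f, method_label = m, subject_id = common,
        reference_value = r[[f]], value = t[[f]],
        excluded = abs(r[[f]]) < min_abs_reference,
        rae = ifelse(.data$excluded, NA_real_,
                     abs(t[[f]] - r[[f]]) / abs(r[[f]]) * 100)
      )
    })
  })

  errors <- per_subject |>
    dplyr::group_by(.data$feature, .data$method_label) |>
    dplyr::summarise(
      mean_rae = mean(.data$rae, na.rm = TRUE),
      sd_rae = stats::sd(.data$rae, na.rm = TRUE),
      n_used = sum(!.data$excluded),
      n_excluded = sum(.data$excluded),
      .groups = "drop"
    )

  tests <- if (length(other_labels) >= 2L) {
    pairs <- utils::combn(other_labels, 2L, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      purrr::map_dfr(feature_names(), function(f) {
        a <- per_subject[per_subject$method_label == pr[1] &
                           per_subject$feature == f, ]
        b <- per_subject[per_subject$method_label == pr[2] &
                           per_subject$feature == f, ]
        common <- intersect(a$subject_id[!a$excluded],
                            b$subject_id[!b$excluded])
        ea <- a$rae[match(common, a$subject_id)]
        eb <- b$rae[match(common, b$subject_id)]
        degenerate <- length(common) < 3L || all(ea == eb) ||
          stats::sd(ea - eb) == 0
        tibble::tibble(
          feature = f, method_a = pr[1], method_b = pr[2],
          n = length(common),
          t_test_p = if (degenerate) NA_real_ else
            unname(stats::t.test(ea, eb, paired = TRUE)$p.value),
          rank_test_p = if (degenerate) NA_real_ else mann_whitney(ea, eb)
        )
      })
    })
  } else {
    tibble::tibble(feature = character(), method_a = character(),
                   method_b = character(), n = integer(),
                   t_test_p = numeric(), rank_test_p = numeric())
  }

  structure(
    list(errors = errors, tests = tests, per_subject = per_subject,
         reference_label = reference_label, threshold_pct = threshold_pct,
         min_abs_reference = min_abs_reference),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> avg.RAE vs %s, threshold %d%%\n",
              x$reference_label, x$threshold_pct))
  print(as.data.frame(x$errors))
  invisible(x)
}

#' Tidy an error report
#'
#' @param x an [feature_error_report()] result.
#' @param ... unused.
#' @return The per-feature, per-method error summary tibble.
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, ...) x$errors

#' One-row summary of an error report
#'
#' @param x an [feature_error_report()] result.
#' @param ... unused.
#' @return A one-row tibble with the grand mean error per method and the
#'   number of features whose method comparison is significant at 0.05.
#' @method glance error_report
#' @export
glance.error_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$errors[, c("feature", "method_label", "mean_rae")],
                             names_from = "method_label",
                             values_from = "mean_rae")
  out <- tibble::tibble(
    reference_label = x$reference_label,
    threshold_pct = x$threshold_pct,
    n_features = length(feature_names()),
    n_significant_t_0.05 = sum(x$tests$t_test_p < 0.05, na.rm = TRUE)
  )
  for (m in setdiff(names(wide), "feature")) {
    out[[paste0("grand_mean_rae_", m)]] <- mean(wide[[m]])
  }
  out
}
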