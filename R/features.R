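#' Six-statistic histogram feature set for masked voxel values
#'
#' Computes the first-order feature set used throughout the analysis:
#' mean, max, min, median, excess kurtosis and skewness of the raw voxel
#' values inside a mask (no histogram binning). Shape statistics use
#' population central moments with divisor n: skewness g1 = m3 / m2^(3/2)
#' and kurtosis = m4 / m2^2 - 3 (Fisher's excess convention, so a
#' platykurtic region has negative kurtosis). No small-sample bias
#' correction is applied.
#'
#' At least 4 values with nonzero variance are required; the fourth-moment
#' statistics are unstable below that.
#'
#' @param values numeric vector of masked voxel values (length >= 4,
#'   finite, nonconstant).
#' @param modality `"ADC"` or `"SUV"`.
#' @param method_label PET reconstruction label (e.g. `"CT_reference"`);
#'   ignored context for ADC.
#' @param zone `"PZ"` or `"TZ"`.
#' @param threshold_pct integer threshold percentage (0 = manual ROI).
#' @return A one-row tibble with columns `modality`, `method_label`,
#'   `zone`, `threshold_pct`, `n_voxels`, `mean`, `max`, `min`, `median`,
#'   `kurtosis`, `skewness`.
#' @export
#' @examples
#' histogram_features(c(0, 0, 1, 1), "SUV", "CT_reference", "PZ", 0)
histogram_features <- function(values, modality = c("SUV", "ADC"),
                               method_label = "CT_reference",
                               zone = c("PZ", "TZ"), threshold_pct = 0L) {
  modality <- match.arg(modality)
  zone <- match.arg(zone)
  values <- as.numeric(values)
  if (length(values) < 4L) {
    stop("need at least 4 voxel values for kurtosis", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    stop("constant region: zero variance, shape statistics undefined",
         call. = FALSE)
  }
  tibble::tibble(
    modality = modality,
    method_label = method_label,
    zone = zone,
    threshold_pct = as.integer(threshold_pct),
    n_voxels = length(values),
    mean = m,
    max = max(values),
    min = min(values),
    median = stats::median(values),
    kurtosis = mean(d^4) / m2^2 - 3,
    skewness = mean(d^3) / m2^1.5
  )
}

feature_names <- function() {
  c("mean", "max", "min", "median", "kurtosis", "skewness")
}

#' Cohort feature table for one PET method and threshold level
#'
#' For each subject: the threshold mask is derived from the *reference*
#' PET's SUV map (threshold 0 uses the manual ROI directly), then both the
#' ADC feature set and the requested method's SUV feature set are computed
#' on that same mask, so feature differences between methods reflect voxel
#' values only, never mask geometry. Subjects whose features cannot be
#' computed (mask too small, constant region) are excluded with a recorded
#' reason, mirroring clinical exclusions.
#'
#' @param cohort list of subjects from [generate_cohort()] or
#'   [read_subject()].
#' @param method_label which PET reconstruction to extract SUV features
#'   from; must exist in every subject's `pet_by_method`.
#' @param threshold_pct integer in \{0, 10, ..., 100\}; 0 means the manual
#'   ROI.
#' @param reference_label the PET method whose SUV map defines the
#'   threshold masks (default `"CT_reference"`).
#' @param b_value_s_mm2 high b-value for the ADC fit (default 800).
#' @return A tibble with one row per subject x modality (ADC, SUV) and the
#'   six feature columns; attribute `exclusions` is a tibble of excluded
#'   subjects and reasons. Errors if fewer than 3 subjects survive.
#' @export
cohort_feature_table <- function(cohort, method_label = "CT_reference",
                                 threshold_pct = 0L,
                                 reference_label = "CT_reference",
                                 b_value_s_mm2 = 800) {
  threshold_pct <- as.integer(threshold_pct)
  rows <- list()
  excl <- list()
  for (subj in cohort) {
    res <- tryCatch(
      subject_features(subj, method_label, threshold_pct, reference_label,
                       b_value_s_mm2),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject_id = subj$subject_id, reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) < 3L) {
    stop(sprintf("only %d subjects usable (< 3); correlation undefined downstream",
                 length(rows)), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(subject_id = character(), reason = character())
  out
}

subject_features <- function(subj, method_label, threshold_pct,
                             reference_label, b_value_s_mm2) {
  if (!method_label %in% names(subj$pet_by_method)) {
    stop(sprintf("subject %s has no PET method '%s'", subj$subject_id,
                 method_label), call. = FALSE)
  }
  if (!reference_label %in% names(subj$pet_by_method)) {
    stop(sprintf("subject %s has no reference PET '%s'", subj$subject_id,
                 reference_label), call. = FALSE)
  }
  suv_ref <- compute_suv(subj$pet_by_method[[reference_label]], subj$dose)
  mask <- if (threshold_pct == 0L) subj$roi else
    threshold_mask(suv_ref, subj$roi, threshold_pct)
  adc <- compute_adc(subj$dwi_b0, subj$dwi_b800, b_value_s_mm2)
  suv <- if (method_label == reference_label) suv_ref else
    compute_suv(subj$pet_by_method[[method_label]], subj$dose)
  dplyr::bind_rows(
    histogram_features(extract_values(adc, mask), "ADC", method_label,
                       subj$roi$zone, threshold_pct),
    histogram_features(extract_values(suv, mask), "SUV", method_label,
                       subj$roi$zone, threshold_pct)
  ) |>
    dplyr::mutate(subject_id = subj$subject_id, .before = 1)
}
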