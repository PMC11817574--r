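#' Injected-dose record for SUV scaling
#'
#' Holds the quantities needed to convert an activity-concentration volume
#' into a body-weight standardized uptake value (SUV) map: injected
#' activity, patient weight, the injection-to-scan delay, and the isotope
#' constants. Defaults are the Ga-68 gamma half-life of 4057.7 s and
#' branching factor 0.89; the branching factor is carried as metadata only,
#' since it enters scanner-side reconstruction, not the SUV formula.
#'
#' @param injected_activity_MBq injected activity at injection time, MBq (> 0).
#' @param body_weight_kg patient body weight, kg (> 0).
#' @param injection_to_scan_s delay between injection and scan start, s (>= 0).
#' @param half_life_s isotope half-life in seconds.
#' @param branching_factor positron branching factor in (0, 1]; metadata only.
#' @return An object of class `dose_record`.
#' @export
#' @examples
#' dose_record(174, 80, 3600)
dose_record <- function(injected_activity_MBq, body_weight_kg,
                        injection_to_scan_s = 0,
                        half_life_s = 4057.7, branching_factor = 0.89) {
  if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0) {
    stop("`injected_activity_MBq` must be positive", call. = FALSE)
  }
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be positive", call. = FALSE)
  }
  if (!is.finite(injection_to_scan_s) || injection_to_scan_s < 0) {
    stop("`injection_to_scan_s` must be nonnegative", call. = FALSE)
  }
  if (!is.finite(half_life_s) || half_life_s <= 0) {
    stop("`half_life_s` must be positive", call. = FALSE)
  }
  if (!is.finite(branching_factor) || branching_factor <= 0 ||
      branching_factor > 1) {
    stop("`branching_factor` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(injected_activity_MBq = injected_activity_MBq,
         body_weight_kg = body_weight_kg,
         injection_to_scan_s = injection_to_scan_s,
         half_life_s = half_life_s,
         branching_factor = branching_factor),
    class = "dose_record"
  )
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf("<dose_record> %.1f MBq injected, %.1f kg, dt = %.0f s (T1/2 = %.1f s)\n",
              x$injected_activity_MBq, x$body_weight_kg,
              x$injection_to_scan_s, x$half_life_s))
  invisible(x)
}

#' Decay-corrected activity at scan start
#'
#' Applies radioactive decay over the injection-to-scan delay:
#' A = A_injected * 2^(-dt / T_half). The correction reference time is scan
#' start; the result is the activity available for SUV normalization.
#'
#' @param dose a [dose_record()].
#' @return Activity at scan start in MBq.
#' @export
#' @examples
#' decay_correct(dose_record(174, 80, injection_to_scan_s = 4057.7))  # 87 MBq
decay_correct <- function(dose) {
  stopifnot(inherits(dose, "dose_record"))
  dose$injected_activity_MBq *
    2^(-dose$injection_to_scan_s / dose$half_life_s)
}

#' Compute an ADC map from two-b-value DWI
#'
#' Mono-exponential inversion of the diffusion signal decay
#' S(b) = S0 * exp(-b * ADC): per voxel ADC = ln(S0 / Sb) / b, reported in
#' units of 1e-3 mm^2/s to match clinical convention. Non-physical voxels
#' (S0 <= 0, Sb <= 0, or Sb > S0, which would give a negative ADC) are
#' clamped to 0 and counted; the count is attached as attribute
#' `n_clamped`.
#'
#' @param b0 [voxel_grid()] of DWI signal at b = 0.
#' @param bhigh [voxel_grid()] of DWI signal at the high b-value.
#' @param b_value_s_mm2 the high b-value in s/mm^2 (> 0); default 800.
#' @return A `voxel_grid` with units `"adc_1e-3_mm2_s"` and attribute
#'   `n_clamped`, the number of clamped voxels.
#' @export
#' @examples
#' b0 <- voxel_grid(array(1000, c(2, 2, 2)), c(2.6, 2.6, 3.12), "signal_au")
#' b8 <- voxel_grid(array(1000 * exp(-0.8), c(2, 2, 2)), c(2.6, 2.6, 3.12),
#'                  "signal_au")
#' adc <- compute_adc(b0, b8, 800)
#' adc$values[1, 1, 1]  # 1.0 (x 1e-3 mm^2/s)
compute_adc <- function(b0, bhigh, b_value_s_mm2 = 800) {
  stopifnot(is_voxel_grid(b0), is_voxel_grid(bhigh))
  stopifnot_congruent(b0, bhigh, "DWI grids")
  if (!is.finite(b_value_s_mm2) || b_value_s_mm2 <= 0) {
    stop("`b_value_s_mm2` must be positive", call. = FALSE)
  }
  s0 <- b0$values
  sb <- bhigh$values
  bad <- s0 <= 0 | sb <= 0 | sb > s0
  adc <- array(0, dim(s0))
  ok <- !bad
  adc[ok] <- log(s0[ok] / sb[ok]) / b_value_s_mm2 * 1000
  out <- voxel_grid(adc, b0$spacing_mm, "adc_1e-3_mm2_s")
  attr(out, "n_clamped") <- sum(bad)
  out
}

#' Compute a body-weight SUV map from an activity-concentration volume
#'
#' SUV = C\[Bq/mL\] * W\[g\] / A_corrected\[Bq\], with tissue density taken
#' as 1 g/mL so SUV is dimensionless. The injected activity is decay
#' corrected to scan start via [decay_correct()]. [suv_to_activity()] is
#' the exact inverse.
#'
#' @param activity [voxel_grid()] of activity concentration in Bq/mL
#'   (nonnegative).
#' @param dose a [dose_record()].
#' @return A `voxel_grid` with units `"suv"`.
#' @export
compute_suv <- function(activity, dose) {
  stopifnot(is_voxel_grid(activity), inherits(dose, "dose_record"))
  if (any(activity$values < 0)) {
    stop("`activity` must be nonnegative", call. = FALSE)
  }
  a_bq <- decay_correct(dose) * 1e6
  if (a_bq <= 0) stop("corrected activity must be positive", call. = FALSE)
  w_g <- dose$body_weight_kg * 1000
  voxel_grid(activity$values * w_g / a_bq, activity$spacing_mm, "suv")
}

#' Convert a SUV map back to activity concentration
#'
#' Inverse of [compute_suv()]: C = SUV * A_corrected / W. Round-tripping
#' through [compute_suv()] reproduces the input exactly (to floating
#' point).
#'
#' @param suv [voxel_grid()] with units `"suv"`.
#' @param dose a [dose_record()].
#' @return A `voxel_grid` with units `"activity_Bq_per_mL"`.
#' @export
suv_to_activity <- function(suv, dose) {
  stopifnot(is_voxel_grid(suv), inherits(dose, "dose_record"))
  a_bq <- decay_correct(dose) * 1e6
  w_g <- dose$body_weight_kg * 1000
  voxel_grid(suv$values * a_bq / w_g, suv$spacing_mm, "activity_Bq_per_mL")
}
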