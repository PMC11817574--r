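#' Lesion region-of-interest mask
#'
#' A boolean voxel mask with its prostate zone label (peripheral zone
#' `"PZ"` or transitional zone `"TZ"`) and provenance: `"manual"` for a
#' delineated lesion ROI, `"thresholded"` for a mask derived from it by
#' percentage-of-SUVmax thresholding (`threshold_pct` 0 is synonymous with
#' manual). Thresholded masks record the SUVmax they were cut from.
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param zone `"PZ"` or `"TZ"`.
#' @param provenance `"manual"` or `"thresholded"`.
#' @param threshold_pct integer percentage of SUVmax (0 for manual masks).
#' @param source_suv_max the ROI SUVmax used for thresholding, or `NA`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, zone = c("PZ", "TZ"),
                     provenance = c("manual", "thresholded"),
                     threshold_pct = 0L, source_suv_max = NA_real_) {
  zone <- match.arg(zone)
  provenance <- match.arg(provenance)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("`mask` must be a logical 3D array", call. = FALSE)
  }
  if (!any(mask)) stop("`mask` must contain at least one voxel", call. = FALSE)
  threshold_pct <- as.integer(threshold_pct)
  if ((provenance == "manual") != (threshold_pct == 0L)) {
    stop("threshold_pct 0 if and only if provenance is manual", call. = FALSE)
  }
  structure(
    list(mask = mask, zone = zone, provenance = provenance,
         threshold_pct = threshold_pct, source_suv_max = source_suv_max),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %s%s, %d voxels\n", x$zone, x$provenance,
              if (x$provenance == "thresholded")
                sprintf(" at %d%% of SUVmax %.3g", x$threshold_pct,
                        x$source_suv_max) else "",
              sum(x$mask)))
  invisible(x)
}

check_mask_congruent <- function(volume, roi) {
  stopifnot(is_voxel_grid(volume), inherits(roi, "roi_mask"))
  if (!identical(dim(volume$values), dim(roi$mask))) {
    stop("mask and volume grids are incongruent", call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximum SUV over an ROI
#'
#' The lesion SUVmax computed over the manually delineated ROI is the
#' anchor for the whole percentage-threshold mask series.
#'
#' @param suv [voxel_grid()] of SUV values.
#' @param roi an [roi_mask()] on the same grid.
#' @return The maximum SUV over the ROI voxels.
#' @export
roi_suv_max <- function(suv, roi) {
  check_mask_congruent(suv, roi)
  max(suv$values[roi$mask])
}

#' Threshold an ROI at a percentage of its SUVmax
#'
#' Keeps the ROI voxels whose SUV is at least `pct`% of the ROI SUVmax
#' (inclusive inequality, so the argmax voxel always survives and the mask
#' is never empty for `pct` <= 100). Thresholding is applied *within* the
#' parent ROI, matching the clinical workflow in which the manual lesion
#' ROI defines both SUVmax and the candidate voxels.
#'
#' @param suv [voxel_grid()] of SUV values.
#' @param roi parent [roi_mask()] (manual, or a coarser threshold mask).
#' @param pct integer threshold percentage in (0, 100].
#' @return A thresholded `roi_mask` recording `pct` and the source SUVmax.
#' @export
#' @examples
#' suv <- voxel_grid(array(1:9, c(3, 3, 1)), c(1, 1, 1), "suv")
#' roi <- roi_mask(array(TRUE, c(3, 3, 1)), "PZ")
#' sum(threshold_mask(suv, roi, 60)$mask)  # 4 voxels: values 6..9
threshold_mask <- function(suv, roi, pct) {
  check_mask_congruent(suv, roi)
  pct <- as.integer(pct)
  if (pct <= 0L || pct > 100L) {
    stop("`pct` must be in (0, 100]", call. = FALSE)
  }
  smax <- roi_suv_max(suv, roi)
  cutoff <- pct / 100 * smax
  mask <- roi$mask & suv$values >= cutoff
  if (!any(mask)) {
    # unreachable with inclusive >=: the argmax voxel satisfies suv >= cutoff
    stop(sprintf("threshold at %d%% of SUVmax %.4g left an empty mask", pct, smax),
         call. = FALSE)
  }
  roi_mask(mask, zone = roi$zone, provenance = "thresholded",
           threshold_pct = pct, source_suv_max = smax)
}

#' Build a nested series of percentage-of-SUVmax masks
#'
#' One mask per threshold, each derived from the same parent ROI, so the
#' series is nested: the mask at a higher percentage is a subset of every
#' mask at a lower percentage.
#'
#' @param suv [voxel_grid()] of SUV values.
#' @param roi parent [roi_mask()].
#' @param pcts strictly increasing integer thresholds; default
#'   `c(10, 20, 30, 40, 50, 60)`.
#' @return A named list of `roi_mask` objects (`"pct10"`, ...).
#' @export
mask_series <- function(suv, roi, pcts = c(10L, 20L, 30L, 40L, 50L, 60L)) {
  pcts <- as.integer(pcts)
  if (length(pcts) == 0L || any(diff(pcts) <= 0)) {
    stop("`pcts` must be strictly increasing", call. = FALSE)
  }
  out <- lapply(pcts, function(p) threshold_mask(suv, roi, p))
  names(out) <- paste0("pct", pcts)
  out
}

#' Extract masked voxel values in a fixed scan order
#'
#' Returns the voxel values at `TRUE` mask positions in column-major array
#' order (first array dimension fastest), the native R storage order, so
#' extraction is reproducible and index arithmetic against the source
#' array is straightforward.
#'
#' @param volume [voxel_grid()] to read from.
#' @param mask an [roi_mask()] on the same grid.
#' @return Numeric vector of length `sum(mask$mask)`.
#' @export
extract_values <- function(volume, mask) {
  check_mask_congruent(volume, mask)
  as.numeric(volume$values[mask$mask])
}
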