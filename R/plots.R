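#' Heatmap of an ADC x SUV correlation grid
#'
#' 6 x 6 annotated tile plot with a symmetric diverging colour scale over
#' \[-1, 1\], ADC features on the rows and SUV features on the columns in
#' the fixed order mean, max, min, median, kurtosis, skewness. Missing
#' cells (degenerate feature columns) are drawn in grey and annotated
#' "NA" rather than interpolated.
#'
#' @param object a [correlation_grid()].
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot correlation_grid
#' @export
autoplot.correlation_grid <- function(object, ...) {
  td <- tidy(object)
  feats <- feature_names()
  td$adc_feature <- factor(td$adc_feature, levels = rev(feats))
  td$suv_feature <- factor(td$suv_feature, levels = feats)
  td$label <- ifelse(is.na(td$rho), "NA", sprintf("%.2f", td$rho))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$suv_feature,
                                   y = .data$adc_feature,
                                   fill = .data$rho)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey80",
                                  name = "Spearman ρ") +
    ggplot2::labs(
      x = "SUV feature", y = "ADC feature",
      title = sprintf("ADC × SUV Spearman correlations (%s)",
                      object$method_label),
      subtitle = sprintf("threshold %d%% of SUVmax, n = %d subjects",
                         object$threshold_pct, object$n)
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Render a correlation-grid heatmap to a file
#'
#' Thin wrapper over [autoplot.correlation_grid()] + [ggplot2::ggsave()]
#' with fixed size and resolution so repeated renders of the same grid
#' are identical.
#'
#' @param grid a [correlation_grid()].
#' @param path output image path (extension selects the device, e.g.
#'   `.png`).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "correlation_grid"))
  p <- autoplot(grid)
  ggplot2::ggsave(path, p, width = 6.5, height = 5.5, dpi = 150)
  invisible(path)
}

#' Bar chart of per-feature attenuation-correction errors
#'
#' Cohort mean avg.RAE per feature and method, with one standard
#' deviation error bars.
#'
#' @param object an [feature_error_report()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  err <- object$errors
  err$feature <- factor(err$feature, levels = feature_names())
  ggplot2::ggplot(err, ggplot2::aes(x = .data$feature, y = .data$mean_rae,
                                    fill = .data$method_label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_rae - .data$sd_rae, 0),
                   ymax = .data$mean_rae + .data$sd_rae),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = "SUV feature", y = "avg.RAE (%)",
                  fill = "AC method",
                  title = sprintf("SUV feature error vs %s",
                                  object$reference_label)) +
    ggplot2::theme_minimal()
}
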