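#' Plot a fitted concentration-response curve
#'
#' Observed mean effects, the fitted sigmoid, and the delta-method
#' function-based confidence band on a log10 concentration axis.
#'
#' @param object A `crc_fit`.
#' @param level Band confidence level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_fit
#' @export
autoplot.crc_fit <- function(object, level = 0.95, ...) {
  bands <- confidence_bands(object, level = level)
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$conc_ugL)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$fci_lwr, ymax = .data$fci_upr),
      fill = "red", alpha = 0.15
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$conc_ugL, y = .data$effect)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (µg/L)", y = "growth inhibition E",
      title = sprintf("%s fit (R2_adj = %.4f)", object$model, object$r2_adj)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ray assessment against its CA and IA predictions
#'
#' Observed means with OCI error bars and the two reference-model
#' prediction curves on the effect axis.
#'
#' @param points Output of [classify_points()].
#' @param prediction Optional [mixture_prediction()] supplying smooth
#'   reference curves; otherwise predictions are drawn at tested points.
#' @return A ggplot object.
#' @export
plot_ray_assessment <- function(points, prediction = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$conc_total_ugL)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$oci_lwr, ymax = .data$oci_upr), width = 0.05
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$effect_mean)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total concentration (µg/L)",
                  y = "growth inhibition E") +
    ggplot2::theme_minimal()
  if (!is.null(prediction)) {
    p <- p +
      ggplot2::geom_line(
        data = prediction$ia,
        ggplot2::aes(x = .data$conc_ugL, y = .data$effect_ca),
        colour = "red", linetype = "dashed"
      ) +
      ggplot2::geom_line(
        data = prediction$ia,
        ggplot2::aes(x = .data$conc_ugL, y = .data$effect_ia),
        colour = "blue", linetype = "dashed"
      )
  } else {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$pred_ca),
                         colour = "red", linetype = "dashed") +
      ggplot2::geom_line(ggplot2::aes(y = .data$pred_ia),
                         colour = "blue", linetype = "dashed")
  }
  p
}
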