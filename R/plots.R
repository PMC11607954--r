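#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Modified Bland-Altman plot
#'
#' Reference HR on the x-axis, difference (radar - reference) on the
#' y-axis, with the mean-difference line (blue) and the mean +/- 1.96 SD
#' limits of agreement (red dashed).
#'
#' @param object A `"bland_altman"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hr_ref, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "reference HR [bpm]",
      y = "HR difference, radar - reference [bpm]",
      title = "Modified Bland-Altman plot",
      subtitle = sprintf("mean %.2f bpm, limits of agreement [%.2f, %.2f] bpm",
                         object$mean_diff, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Method-comparison scatter plot
#'
#' Radar HR against reference HR with the angle bisector (dashed) and the
#' least-squares regression line (solid).
#'
#' @param object An `"hr_regression"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hr_regression <- function(object, ...) {
  rng <- range(c(object$data$hr_ref, object$data$hr_radar))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hr_ref, y = .data$hr_radar)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "blue") +
    ggplot2::coord_fixed(xlim = rng, ylim = rng) +
    ggplot2::labs(
      x = "reference HR [bpm]", y = "radar HR [bpm]",
      title = "Radar vs reference heart rate",
      subtitle = sprintf("y = %.2f + %.2f x (n = %d)",
                         object$intercept, object$slope, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a heart-rate series
#'
#' Time course of an aggregated HR series; invalidated values are shown in
#' grey.
#'
#' @param hr An HR tibble from [interval_mean_hr()], [rolling_mean_hr()] or
#'   [block_mean_hr()].
#' @return A ggplot.
#' @export
plot_hr_series <- function(hr) {
  tcol <- intersect(c("time_s", "interval_start_s"), names(hr))[1]
  d <- dplyr::mutate(hr, .t = .data[[tcol]] / 60,
                     .valid = if ("valid" %in% names(hr)) .data$valid else TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.t, y = .data$hr_bpm,
                                  colour = .data$.valid)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                 guide = "none") +
    ggplot2::labs(x = "time [min]", y = "HR [bpm]") +
    ggplot2::theme_minimal()
}
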