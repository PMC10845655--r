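#' Publication-style plots for agreement results
#'
#' Each result object has a dedicated ggplot builder; `autoplot()` methods
#' dispatch to them. Every quantity shown is also available numerically from
#' the corresponding result object.
#'
#' @param x A result object (`ba_result`, `roc_result`, `polar_result`,
#'   `error_grid_result`, or `waveform_record`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
plot_bland_altman <- function(x, ...) {
  stopifnot(inherits(x, "ba_result"))
  ggplot2::ggplot(x$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = x$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(x$loa_low, x$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Mean of methods (g/L)", y = "Test - reference (g/L)",
      title = sprintf("Bias %.2f g/L, LOA %.2f to %.2f g/L (PE %.1f%%)",
                      x$bias, x$loa_low, x$loa_high, x$percentage_error)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
plot_roc <- function(x, ...) {
  stopifnot(inherits(x, "roc_result"))
  curve <- dplyr::arrange(x$curve, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.2f (95%% CI %.2f-%.2f)",
                      x$auc, x$auc_ci[1], x$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
plot_polar_trend <- function(x, ...) {
  stopifnot(inherits(x, "polar_result"))
  pts <- x$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$angle_deg, y = abs(.data$radius),
                                    colour = .data$excluded)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-x$limit_deg, x$limit_deg),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = x$exclusion_radius, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey70")) +
    ggplot2::coord_polar(theta = "x", start = pi) +
    ggplot2::xlim(-180, 180) +
    ggplot2::labs(
      x = "Angle from identity direction (deg)", y = "|Mean change| (g/L)",
      title = sprintf("Concordance %.1f%% within +/-%g deg",
                      x$concordance_rate, x$limit_deg)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname plots
#' @export
plot_error_grid <- function(x, ...) {
  stopifnot(inherits(x, "error_grid_result"))
  th <- x$thresholds
  lim <- range(c(x$pairs$ref, x$pairs$test, th)) + c(-5, 5)
  ggplot2::ggplot(x$pairs, ggplot2::aes(x = .data$ref, y = .data$test,
                                        colour = .data$zone)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = th, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = th, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(A = "forestgreen", B = "orange",
                                            C = "red")) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(
      x = "Reference Hb (g/L)", y = "Test Hb (g/L)",
      title = sprintf("Zones A/B/C: %.0f%% / %.0f%% / %.0f%%",
                      x$zones$pct[1], x$zones$pct[2], x$zones$pct[3])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
plot_waveform <- function(x, ...) {
  stopifnot(inherits(x, "waveform_record"))
  df <- as.data.frame(x) |>
    tidyr::pivot_longer(c("red_v", "inf_v"),
                        names_to = "channel", values_to = "voltage_v")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$voltage_v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Voltage (V)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.ba_result <- function(x, ...) plot_bland_altman(x, ...)

#' @rdname plots
#' @export
autoplot.roc_result <- function(x, ...) plot_roc(x, ...)

#' @rdname plots
#' @export
autoplot.polar_result <- function(x, ...) plot_polar_trend(x, ...)

#' @rdname plots
#' @export
autoplot.error_grid_result <- function(x, ...) plot_error_grid(x, ...)

#' @rdname plots
#' @export
autoplot.waveform_record <- function(x, ...) plot_waveform(x, ...)
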