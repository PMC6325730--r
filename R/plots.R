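#' Plot a precision grid
#'
#' Expected Wald half-width against sample size, one line per treatment
#' frequency, on a log-scaled n axis. The companion detection view
#' (`what = "detection"`) shows the probability of observing the treatment
#' at least once.
#'
#' @param object A [precision_grid()].
#' @param what `"halfwidth"` (default) or `"detection"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @family presentation
#' @export
autoplot.precision_grid <- function(object, what = c("halfwidth",
                                                     "detection"), ...) {
  what <- match.arg(what)
  yvar <- if (what == "halfwidth") "halfwidth" else "detection_prob"
  ylab <- if (what == "halfwidth") {
    "Expected 95% CI half-width"
  } else {
    "Probability of observing the treatment at least once"
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n, y = .data[[yvar]],
    colour = factor(.data$p), group = factor(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = unique(object$n)) +
    ggplot2::labs(x = "Number of charts (n)", y = ylab,
                  colour = "Treatment\nfrequency p") +
    ggplot2::theme_minimal()
}

#' Plot a sample-size-versus-dispersion curve
#'
#' @param object A [samplesize_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @family presentation
#' @export
autoplot.samplesize_curve <- function(object, ...) {
  v <- attr(object, "target_relative_width")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cv, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Coefficient of variation (sd / mean)",
      y = "Required sample size",
      title = sprintf(
        "Sample size for a 95%% CI within ±%g%% of the mean cost",
        100 * v)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulation result against its closed form
#'
#' Point estimate with a +/- 3 Monte Carlo standard error bar, alongside
#' the closed-form value the simulation checks (dashed line).
#'
#' @param object A `sim_result` (possibly several rows bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @family simulation
#' @export
autoplot.sim_result <- function(object, ...) {
  df <- dplyr::mutate(object, run = factor(seq_len(dplyr::n())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 3 * .data$mc_se,
      ymax = .data$estimate + 3 * .data$mc_se)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$closed_form),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Estimate ± 3 MC standard errors") +
    ggplot2::theme_minimal()
}
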