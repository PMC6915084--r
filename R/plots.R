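#' Plot a modulation function
#'
#' Line plot of the modulation function over time; pulses (local maxima)
#' can be overlaid as vertical lines.
#'
#' @param object A [modulation_function()].
#' @param pulses Optional `pulse_train` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modulation_function <- function(object, pulses = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s modulation", attr(object, "kind")),
                  title = sprintf("Modulation function (cutoff %s Hz)",
                                  format(attr(object, "cutoff")))) +
    ggplot2::theme_minimal()
  if (!is.null(pulses)) {
    p <- p + ggplot2::geom_vline(data = as_tibble(pulses),
                                 ggplot2::aes(xintercept = .data$time),
                                 colour = "purple", alpha = 0.6,
                                 linetype = "dashed")
  }
  p
}

#' Plot a lag profile
#'
#' Median windowed correlation (and the percentage of positive correlation
#' samples) against signal lag, with optional extrema annotations.
#'
#' @param object A `lag_profile` from [lag_sweep()].
#' @param extrema Optional `lag_extrema` annotation from
#'   [find_lag_extrema()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lag_profile <- function(object, extrema = NULL, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("median_rho", "pct_positive"),
                        names_to = "panel", values_to = "value") |>
    mutate(panel = factor(.data$panel, c("median_rho", "pct_positive"),
                          c("median correlation", "% positive")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "lag (ms, positive = articulatory delayed)", y = NULL,
                  title = sprintf("Lag profile (eta = %g)", attr(object, "eta"))) +
    ggplot2::theme_minimal()
  if (!is.null(extrema)) {
    marks <- tidy(extrema)
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$lag_ms,
                                              colour = .data$type),
                                 linetype = "dotted") +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot pulse tallies by syllable class
#'
#' Box plots of per-speaker mean pulse counts for open, single-coda, and
#' multi-coda syllables.
#'
#' @param tallies A tibble of per-speaker class means (as in the `tallies`
#'   element of a [run_pipeline()] report: columns `speaker`, `coda_class`,
#'   `mean_pulses`), or a single `syllable_tally`.
#' @return A ggplot object.
#' @export
plot_syllable_tallies <- function(tallies) {
  if (inherits(tallies, "syllable_tally")) tallies <- tallies$class_means
  ggplot2::ggplot(tallies, ggplot2::aes(x = .data$coda_class,
                                        y = .data$mean_pulses)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "syllable type", y = "mean pulses per syllable") +
    ggplot2::theme_minimal()
}

#' Plot original vs surrogate correlation magnitudes
#'
#' Box plots of `|selected r|` per condition and window sharpness, the
#' standard view of the surrogate contrast.
#'
#' @param extremes The `extremes` table of a [run_pipeline()] report
#'   (columns `speaker`, `condition`, `eta`, `selected_r`).
#' @return A ggplot object.
#' @export
plot_surrogate_contrast <- function(extremes) {
  ggplot2::ggplot(extremes,
                  ggplot2::aes(x = factor(.data$eta), y = abs(.data$selected_r),
                               fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "eta (window sharpness)", y = "|correlation|",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
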