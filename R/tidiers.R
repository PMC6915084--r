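#' Tidy a pulse train
#'
#' @param x A `pulse_train` from [detect_pulses()].
#' @param ... Unused.
#' @return A tibble with `frame`, `time`, `value`, and `interval` (time
#'   since the previous pulse; `NA` for the first).
#' @export
tidy.pulse_train <- function(x, ...) {
  as_tibble(x) |> mutate(interval = c(NA_real_, diff(.data$time)))
}

#' Glance at a pulse train
#'
#' @param x A `pulse_train`.
#' @param ... Unused.
#' @return The one-row [interpulse_summary()] tibble.
#' @export
glance.pulse_train <- function(x, ...) interpulse_summary(x)

#' Tidy a syllable tally
#'
#' @param x A `syllable_tally` from [tally_pulses_by_syllable()].
#' @param ... Unused.
#' @return The per-coda-class means tibble.
#' @export
tidy.syllable_tally <- function(x, ...) x$class_means

#' Glance at a syllable tally
#'
#' @param x A `syllable_tally`.
#' @param ... Unused.
#' @return One-row tibble: `n_syllables`, `n_pulses_assigned`,
#'   `mean_pulses`.
#' @export
glance.syllable_tally <- function(x, ...) {
  tibble(n_syllables = nrow(x$per_syllable),
         n_pulses_assigned = sum(x$per_syllable$n_pulses),
         mean_pulses = mean(x$per_syllable$n_pulses))
}

#' Tidy a lag profile
#'
#' @param x A `lag_profile` from [lag_sweep()].
#' @param ... Unused.
#' @return A tibble with `lag_frames`, `lag_ms`, `median_rho`,
#'   `pct_positive`.
#' @export
tidy.lag_profile <- function(x, ...) as_tibble(x)

#' Glance at a lag profile
#'
#' @param x A `lag_profile`.
#' @param ... Unused.
#' @return One-row tibble: `eta`, `primary_max_lag_ms`, `max_median_rho`,
#'   `min_median_rho`.
#' @export
glance.lag_profile <- function(x, ...) {
  tibble(eta = attr(x, "eta"),
         primary_max_lag_ms = attr(x, "primary_max_lag_ms"),
         max_median_rho = max(x$median_rho),
         min_median_rho = min(x$median_rho))
}

#' Tidy lag extrema annotations
#'
#' @param x A `lag_extrema` from [find_lag_extrema()].
#' @param ... Unused.
#' @return A tibble of the annotated extrema (`type`, `side`, `lag_ms`,
#'   `lag_ref_ms`, `rho`).
#' @export
tidy.lag_extrema <- function(x, ...) {
  bind_rows(
    tibble(type = "primary_max", side = NA_character_,
           lag_ms = x$primary_max_lag_ms, lag_ref_ms = 0,
           rho = x$primary_max_rho),
    if (nrow(x$minima) > 0) mutate(x$minima, type = "minimum",
                                   lag_ref_ms = NA_real_, .before = 1),
    if (nrow(x$secondary) > 0) mutate(x$secondary, type = "secondary_max",
                                      .before = 1)
  )
}

#' Glance at lag extrema
#'
#' @param x A `lag_extrema`.
#' @param ... Unused.
#' @return One-row tibble: `primary_max_lag_ms`, `primary_max_rho`,
#'   `secondary_lag_avg_ms`, `has_secondary`, `one_sided`.
#' @export
glance.lag_extrema <- function(x, ...) {
  tibble(primary_max_lag_ms = x$primary_max_lag_ms,
         primary_max_rho = x$primary_max_rho,
         secondary_lag_avg_ms = x$secondary_lag_avg_ms,
         has_secondary = x$has_secondary,
         one_sided = x$one_sided)
}

#' Tidy a sign test result
#'
#' @param x A `sign_test_result` from [sign_test()].
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_positive`, `p_value`.
#' @export
tidy.sign_test_result <- function(x, ...) as_tibble(unclass(x))

#' Tidy a surrogate comparison
#'
#' @param x A `surrogate_comparison` from
#'   [compare_original_vs_surrogate()].
#' @param ... Unused.
#' @return The per-eta sign-test tibble.
#' @export
tidy.surrogate_comparison <- function(x, ...) x$sign_tests

#' Glance at a surrogate comparison
#'
#' @param x A `surrogate_comparison`.
#' @param ... Unused.
#' @return The lag-dispersion summary tibble (per eta x condition).
#' @export
glance.surrogate_comparison <- function(x, ...) x$lag_summary
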