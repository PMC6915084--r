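#' Half-swap surrogate of a series
#'
#' Builds the null-hypothesis partner of a signal pair by swapping the two
#' halves of one series (split at `floor(n / 2)`): the output is the second
#' half followed by the first. Pairing the result with the unchanged partner
#' destroys the causal temporal alignment while preserving the marginal
#' distribution of values; any remaining correlation reflects generic
#' properties of signals of this type.
#'
#' @param series Numeric series of length >= 2.
#' @return The half-swapped series (same multiset of values).
#' @export
make_surrogate <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2) abort("Series too short.", class = "comod_insufficient_data")
  n2 <- n %/% 2
  c(x[(n2 + 1):n], x[seq_len(n2)])
}

#' Exact two-sided sign test
#'
#' Exact binomial test on the signs of paired differences; zero differences
#' are dropped (standard exact sign test). With no nonzero differences the
#' result is undefined (`p_value = NA`).
#'
#' @param differences Numeric vector of signed paired differences.
#' @return A one-row tibble of class `sign_test_result`: `n_pairs` (nonzero
#'   differences), `n_positive`, `p_value`.
#' @export
sign_test <- function(differences) {
  d <- differences[!is.na(differences) & differences != 0]
  n <- length(d)
  k <- sum(d > 0)
  p <- if (n == 0) NA_real_ else binom.test(k, n, p = 0.5)$p.value
  out <- tibble(n_pairs = n, n_positive = k, p_value = p)
  class(out) <- c("sign_test_result", class(out))
  out
}

#' Per-speaker extreme correlations of a lag profile
#'
#' Finds the maximum positive and maximum negative values of the median
#' correlation across lags, with the lags at which they occur, and selects
#' the one with higher magnitude as the speaker's representative
#' correlation (ties break toward the positive extreme). A profile with no
#' negative (or no positive) values leaves that side `NA`.
#'
#' @param profile A `lag_profile` from [lag_sweep()].
#' @return One-row tibble: `max_pos_r`, `lag_pos_ms`, `max_neg_r`,
#'   `lag_neg_ms`, `selected_r`, `selected_lag_ms`.
#' @export
select_speaker_extreme <- function(profile) {
  v <- profile$median_rho
  lag <- profile$lag_ms
  pos_i <- if (any(v > 0)) which.max(v) else NA_integer_
  neg_i <- if (any(v < 0)) which.min(v) else NA_integer_
  max_pos <- if (is.na(pos_i)) NA_real_ else v[pos_i]
  max_neg <- if (is.na(neg_i)) NA_real_ else v[neg_i]
  if (is.na(neg_i) || (!is.na(pos_i) && abs(max_pos) >= abs(max_neg))) {
    sel <- max_pos; sel_lag <- if (is.na(pos_i)) NA_real_ else lag[pos_i]
  } else {
    sel <- max_neg; sel_lag <- lag[neg_i]
  }
  tibble(max_pos_r = max_pos,
         lag_pos_ms = if (is.na(pos_i)) NA_real_ else lag[pos_i],
         max_neg_r = max_neg,
         lag_neg_ms = if (is.na(neg_i)) NA_real_ else lag[neg_i],
         selected_r = sel,
         selected_lag_ms = sel_lag)
}

#' Compare original and surrogate correlations across speakers
#'
#' The conservative comparison of original against surrogate signal pairs:
#' a sign test on `|original r| - |surrogate r|` per speaker (surrogate
#' correlations vary in sign, so magnitudes are compared), run separately
#' for each `eta`, plus a summary of the medians and standard deviations of
#' the lags of the positive and negative extremes for each condition
#' (original lags cluster tightly near zero; surrogate lags scatter).
#'
#' @param results A tibble with one row per speaker x condition x eta, with
#'   columns `speaker`, `condition` (`"original"`/`"surrogate"`), `eta`, and
#'   the columns of [select_speaker_extreme()].
#' @return A list of class `surrogate_comparison`: `sign_tests` (per eta:
#'   n, positive count, p), `lag_summary` (per eta x condition: median/SD of
#'   positive- and negative-extreme lags).
#' @export
compare_original_vs_surrogate <- function(results) {
  res <- as_tibble(results)
  needed <- c("speaker", "condition", "eta", "selected_r",
              "lag_pos_ms", "lag_neg_ms")
  if (!all(needed %in% names(res))) {
    abort(paste("results must have columns:", paste(needed, collapse = ", ")),
          class = "comod_format_error")
  }
  wide <- res |>
    select("speaker", "condition", "eta", "selected_r") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "selected_r")
  if (!all(c("original", "surrogate") %in% names(wide)) ||
      anyNA(wide$original) || anyNA(wide$surrogate)) {
    abort("Every speaker needs both an original and a surrogate result.",
          class = "comod_validation_error")
  }
  tests <- wide |>
    group_by(.data$eta) |>
    summarise(sign_test(abs(.data$original) - abs(.data$surrogate)),
              .groups = "drop")
  lag_summary <- res |>
    group_by(.data$eta, .data$condition) |>
    summarise(median_lag_pos_ms = median(.data$lag_pos_ms, na.rm = TRUE),
              sd_lag_pos_ms = sd(.data$lag_pos_ms, na.rm = TRUE),
              median_lag_neg_ms = median(.data$lag_neg_ms, na.rm = TRUE),
              sd_lag_neg_ms = sd(.data$lag_neg_ms, na.rm = TRUE),
              .groups = "drop")
  structure(list(sign_tests = tests, lag_summary = lag_summary),
            class = "surrogate_comparison")
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat("<surrogate_comparison>\nSign tests (|original| - |surrogate|):\n")
  print(x$sign_tests)
  cat("Lag-of-extreme summary:\n")
  print(x$lag_summary)
  invisible(x)
}

#' Overall correlation with a permutation p-value
#'
#' Plain Pearson correlation over the full pair of series (the "overall"
#' correlation contrasted with windowed medians), with a significance level
#' from a seeded permutation null (shuffling one series).
#'
#' @param x,y Numeric series of equal length.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draw.
#' @return One-row tibble: `r`, `p_value`, `n_perm`.
#' @export
overall_correlation <- function(x, y, n_perm = 199, seed = 1L) {
  r <- cor(x, y)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) cor(sample(x), y), numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(r))) / (n_perm + 1)
  tibble(r = r, p_value = p, n_perm = as.integer(n_perm))
}
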