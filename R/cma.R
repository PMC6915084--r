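#' Exponential correlation kernel
#'
#' Builds the symmetric exponentially decaying kernel `w(l) = c * exp(-eta
#' * |l|)` used by correlation map analysis. The infinite support is
#' truncated at the smallest lag `L` with `exp(-eta * L) < tolerance`, and
#' the normalizer `c` is chosen so the truncated weights sum to exactly 1.
#' Larger `eta` gives a sharper (narrower) window and a higher effective
#' frequency cutoff (see [eta_to_cutoff()]).
#'
#' @param eta Window sharpness, > 0 (per-frame decay rate).
#' @param tolerance Truncation tolerance in (0, 1).
#' @return A list of class `kernel_spec`: `eta`, `c`, `truncation_lag`,
#'   `lags` (`-L:L`), `weights`.
#' @export
kernel_weights <- function(eta, tolerance = 1e-8) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) {
    abort("eta must be a single positive number.", class = "comod_parameter_error")
  }
  if (tolerance <= 0 || tolerance >= 1) {
    abort("tolerance must be in (0, 1).", class = "comod_parameter_error")
  }
  L <- as.integer(floor(log(1 / tolerance) / eta)) + 1L
  lags <- -L:L
  w <- exp(-eta * abs(lags))
  cnorm <- 1 / sum(w)
  structure(list(eta = eta, c = cnorm, truncation_lag = L,
                 lags = lags, weights = w * cnorm),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: eta = %g, truncation lag = %d frames, sum(w) = %.12f>\n",
              x$eta, x$truncation_lag, sum(x$weights)))
  invisible(x)
}

# Kernel-weighted moving sums via FFT convolution; out[i] = sum_l w(l) v(i-l).
kernel_convolve <- function(v, kernel) {
  n <- length(v)
  L <- kernel$truncation_lag
  full <- convolve(v, rev(kernel$weights), type = "open")
  full[(L + 1):(L + n)]
}

#' Kernel-windowed correlation between two series (correlation map analysis)
#'
#' Computes a correlation value at every sample: covariance and variances
#' are exponentially weighted sums centred on each sample (kernel from
#' [kernel_weights()]), and their ratio gives a per-sample correlation
#' coefficient. With `center = TRUE` (default) the kernel-weighted local
#' means are removed first, i.e. a weighted Pearson correlation per sample;
#' with `center = FALSE` the raw (uncentred) product form is used. Near the
#' series boundaries the kernel mass falling outside the series is
#' renormalized over the available samples. Samples where either series has
#' (numerically) zero local variance get `NA`.
#'
#' @param x,y Numeric series of equal length (>= 2).
#' @param kernel A `kernel_spec`, or a single `eta` value.
#' @param center Remove weighted local means before the covariance?
#' @param lag Signed frame shift recorded on the result (bookkeeping only;
#'   apply shifts before calling, as [lag_sweep()] does).
#' @return A tibble of class `correlation_series` with columns `frame`,
#'   `rho` (clamped to `[-1, 1]`); attributes `eta`, `lag`, `centered`.
#' @export
cma_correlate <- function(x, y, kernel, center = TRUE, lag = 0L) {
  if (is.numeric(kernel)) kernel <- kernel_weights(kernel)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "comod_parameter_error")
  }
  n <- length(x)
  if (n < 2) abort("Series too short.", class = "comod_insufficient_data")
  mass <- kernel_convolve(rep(1, n), kernel)
  sxy <- kernel_convolve(x * y, kernel) / mass
  sxx <- kernel_convolve(x * x, kernel) / mass
  syy <- kernel_convolve(y * y, kernel) / mass
  if (center) {
    mx <- kernel_convolve(x, kernel) / mass
    my <- kernel_convolve(y, kernel) / mass
    sxy <- sxy - mx * my
    sxx <- sxx - mx * mx
    syy <- syy - my * my
  }
  # declare zero local variance where the centred second moment vanishes
  # relative to the raw one (catches constants exactly, tolerates fft noise)
  msx <- kernel_convolve(x * x, kernel) / mass
  msy <- kernel_convolve(y * y, kernel) / mass
  bad <- sxx <= 1e-12 * pmax(msx, .Machine$double.xmin) |
    syy <= 1e-12 * pmax(msy, .Machine$double.xmin)
  rho <- rep(NA_real_, n)
  ok <- !bad
  rho[ok] <- pmin(1, pmax(-1, sxy[ok] / sqrt(sxx[ok] * syy[ok])))
  out <- tibble(frame = seq_len(n), rho = rho)
  attr(out, "eta") <- kernel$eta
  attr(out, "lag") <- lag
  attr(out, "centered") <- center
  class(out) <- c("correlation_series", class(out))
  out
}

#' Median of a correlation series
#'
#' Median over the defined (non-`NA`) samples of the correlation function.
#'
#' @param series A `correlation_series` (or numeric vector of correlations).
#' @return The median correlation.
#' @export
median_correlation <- function(series) {
  rho <- if (is.numeric(series)) series else series$rho
  if (all(is.na(rho))) {
    abort("Correlation undefined at every sample.", class = "comod_insufficient_data")
  }
  median(rho, na.rm = TRUE)
}

# Percentage of defined correlation samples that are positive.
pct_positive <- function(rho) {
  rho <- rho[!is.na(rho)]
  if (length(rho) == 0) return(NA_real_)
  100 * mean(rho > 0)
}

#' Sweep the windowed correlation across signal lags
#'
#' For each integer frame shift within `+/- lag_range_ms`, delays `x`
#' (the articulatory role; positive lag = `x` delayed with respect to `y`)
#' by that many frames, computes the windowed correlation over the
#' overlapping span, and records the median correlation and the percentage
#' of positive correlation samples. The lag grid is integer frame shifts
#' reported in ms (`shift * 1000 / frame_rate`).
#'
#' @param x,y Numeric series of equal length (x plays the articulatory,
#'   y the acoustic role).
#' @param kernel A `kernel_spec` or single `eta`.
#' @param lag_range_ms Half-width of the lag sweep, ms.
#' @param frame_rate Frame rate, Hz.
#' @param center Passed to [cma_correlate()].
#' @return A tibble of class `lag_profile` with columns `lag_frames`,
#'   `lag_ms`, `median_rho`, `pct_positive`; attributes `frame_rate`, `eta`,
#'   and `primary_max_lag_ms` (lag of the maximum median correlation).
#' @export
lag_sweep <- function(x, y, kernel, lag_range_ms = 200, frame_rate,
                      center = TRUE) {
  if (is.numeric(kernel)) kernel <- kernel_weights(kernel)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "comod_parameter_error")
  }
  n <- length(x)
  S <- as.integer(floor(lag_range_ms / 1000 * frame_rate))
  if (S >= n / 2) {
    abort("lag range exceeds half the series length.", class = "comod_parameter_error")
  }
  rows <- purrr::map(-S:S, function(s) {
    if (s >= 0) {
      xs <- x[seq_len(n - s)]
      ys <- y[seq.int(1 + s, n)]
    } else {
      xs <- x[seq.int(1 - s, n)]
      ys <- y[seq_len(n + s)]
    }
    cs <- cma_correlate(xs, ys, kernel, center = center, lag = s)
    tibble(lag_frames = s,
           lag_ms = s * 1000 / frame_rate,
           median_rho = median_correlation(cs),
           pct_positive = pct_positive(cs$rho))
  })
  out <- bind_rows(rows)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "eta") <- kernel$eta
  attr(out, "primary_max_lag_ms") <- out$lag_ms[which.max(out$median_rho)]
  class(out) <- c("lag_profile", class(out))
  out
}

# Local extrema (frame indices into a vector) with plateau-first rule.
local_extrema_idx <- function(v, maxima = TRUE) {
  if (!maxima) v <- -v
  s <- sign(diff(v))
  peaks <- integer(0)
  for (i in which(s > 0)) {
    j <- i + 1
    while (j <= length(s) && s[j] == 0) j <- j + 1
    if (j <= length(s) && s[j] < 0) peaks <- c(peaks, i + 1L)
  }
  peaks
}

#' Find lag-profile extrema and the shared repetition period
#'
#' Mirrors the autocorrelation-style reading of a lag profile. The primary
#' maximum is the lag of the highest median correlation. On each side of
#' lag 0, the correlation minimum closest to zero is located; a secondary
#' maximum is then sought between that minimum and `+/- search_limit_ms`
#' (the most extreme of multiple nearby maxima is chosen). Each secondary
#' lag is referenced to the primary-maximum lag (subtracting it), and the
#' positive referenced lag and the absolute value of the negative one are
#' averaged into a single shared-period estimate. Sides without a minimum
#' or without a secondary maximum are flagged missing; the average then
#' uses the available side(s).
#'
#' @param profile A `lag_profile` from [lag_sweep()].
#' @param search_limit_ms Outer search limit for secondary maxima, ms.
#' @return A list of class `lag_extrema`: `primary_max_lag_ms`,
#'   `primary_max_rho`, `minima` and `secondary` tibbles (columns `side`,
#'   `lag_ms`, `rho`, and for secondary `lag_ref_ms`), `secondary_lag_avg_ms`,
#'   `has_secondary`, `one_sided`.
#' @export
find_lag_extrema <- function(profile, search_limit_ms = 170) {
  if (max(abs(profile$lag_ms)) < search_limit_ms - 1e-9) {
    abort("Profile does not cover the secondary-maximum search limit.",
          class = "comod_parameter_error")
  }
  v <- profile$median_rho
  lag <- profile$lag_ms
  primary_i <- which.max(v)
  primary_lag <- lag[primary_i]
  min_idx <- local_extrema_idx(v, maxima = FALSE)

  # secondary maximum = argmax of the profile on the interval between the
  # near-zero minimum and the search limit (the most extreme of multiple
  # nearby maxima); requires a minimum on that side to exist
  side_result <- function(sgn) {
    mins <- min_idx[sign(lag[min_idx]) == sgn]
    if (length(mins) == 0) {
      return(list(min = NULL, sec = NULL))
    }
    m <- mins[which.min(abs(lag[mins]))]
    if (sgn > 0) {
      cand <- which(lag > lag[m] & lag <= search_limit_ms)
    } else {
      cand <- which(lag < lag[m] & lag >= -search_limit_ms)
    }
    sec <- if (length(cand) > 0) cand[which.max(v[cand])] else NULL
    list(min = m, sec = sec)
  }
  pos <- side_result(+1)
  neg <- side_result(-1)

  minima <- bind_rows(
    if (!is.null(neg$min)) tibble(side = "negative", lag_ms = lag[neg$min], rho = v[neg$min]),
    if (!is.null(pos$min)) tibble(side = "positive", lag_ms = lag[pos$min], rho = v[pos$min])
  )
  secondary <- bind_rows(
    if (!is.null(neg$sec)) tibble(side = "negative", lag_ms = lag[neg$sec],
                                  lag_ref_ms = lag[neg$sec] - primary_lag,
                                  rho = v[neg$sec]),
    if (!is.null(pos$sec)) tibble(side = "positive", lag_ms = lag[pos$sec],
                                  lag_ref_ms = lag[pos$sec] - primary_lag,
                                  rho = v[pos$sec])
  )
  refs <- c(if (!is.null(pos$sec)) lag[pos$sec] - primary_lag,
            if (!is.null(neg$sec)) abs(lag[neg$sec] - primary_lag))
  structure(list(primary_max_lag_ms = primary_lag,
                 primary_max_rho = v[primary_i],
                 minima = minima,
                 secondary = secondary,
                 secondary_lag_avg_ms = if (length(refs) > 0) mean(refs) else NA_real_,
                 has_secondary = length(refs) > 0,
                 one_sided = length(refs) == 1),
            class = "lag_extrema")
}

#' @export
print.lag_extrema <- function(x, ...) {
  cat(sprintf("<lag_extrema: primary max at %.1f ms (rho = %.3f); %s>\n",
              x$primary_max_lag_ms, x$primary_max_rho,
              if (!x$has_secondary) "no secondary maxima" else
                sprintf("secondary lag avg = %.1f ms%s", x$secondary_lag_avg_ms,
                        if (x$one_sided) " (one-sided)" else "")))
  invisible(x)
}

#' Threshold lag where positive correlations drop below 50%
#'
#' Searches outward from the primary maximum of the lag profile, in each
#' direction, for the first lag at which the percentage of positive
#' correlation samples falls under 50%; the two distances (in ms from the
#' primary maximum) are averaged. A direction that never drops below 50%
#' within the grid is flagged unbounded and excluded from the average; the
#' threshold is `NA` when both directions are unbounded.
#'
#' @param profile A `lag_profile` from [lag_sweep()].
#' @return One-row tibble: `threshold_ms`, `left_ms`, `right_ms`,
#'   `unbounded` (logical).
#' @export
positive_threshold_lag <- function(profile) {
  if (all(is.na(profile$pct_positive))) {
    abort("pct_positive undefined over the grid.", class = "comod_insufficient_data")
  }
  i0 <- which.max(profile$median_rho)
  lag <- profile$lag_ms
  p <- profile$pct_positive
  scan <- function(idx) {
    drop <- idx[which(p[idx] < 50)]
    if (length(drop) == 0) NA_real_ else abs(lag[drop[1]] - lag[i0])
  }
  right <- scan(seq.int(i0, nrow(profile)))
  left <- scan(rev(seq_len(i0)))
  both <- c(left, right)
  tibble(threshold_ms = if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE),
         left_ms = left, right_ms = right,
         unbounded = anyNA(both))
}

#' Effective frequency cutoff of the correlation kernel
#'
#' The exponential kernel acts as a low-pass on the correlation time
#' function; this computes its -3 dB point numerically from the discrete
#' frequency response of the truncated, normalized kernel,
#' `H(w) = w0 + 2 * sum_l w_l cos(w l)` (real, `H(0) = 1`), at a given
#' frame rate. The cutoff increases monotonically with `eta`; in the
#' small-`eta` limit it approaches `eta * sqrt(sqrt(2) - 1)` rad/frame.
#'
#' @param eta Kernel sharpness value(s), > 0.
#' @param frame_rate Frame rate, Hz.
#' @param tolerance Kernel truncation tolerance.
#' @return Cutoff frequency (Hz), vectorized over `eta`.
#' @export
eta_to_cutoff <- function(eta, frame_rate = 145.6, tolerance = 1e-8) {
  vapply(eta, function(e) {
    k <- kernel_weights(e, tolerance)
    L <- k$truncation_lag
    wpos <- k$weights[(L + 2):(2 * L + 1)]
    H <- function(omega) {
      k$weights[L + 1] + 2 * vapply(omega, function(o) sum(wpos * cos(o * seq_len(L))),
                                    numeric(1))
    }
    target <- 1 / sqrt(2)
    lo <- 0; hi <- pi
    # H is monotone decreasing near 0 up to its first crossing; bisect on a
    # bracket found by coarse scan
    grid <- seq(0, pi, length.out = 4096)
    hv <- H(grid)
    ix <- which(hv < target)[1]
    if (is.na(ix)) return(frame_rate / 2)
    lo <- grid[ix - 1]; hi <- grid[ix]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (H(mid) >= target) lo <- mid else hi <- mid
    }
    ((lo + hi) / 2) / (2 * pi) * frame_rate
  }, numeric(1))
}

#' Write a lag profile as CSV with an annotation sidecar
#'
#' @param profile A `lag_profile`.
#' @param path Output CSV path (columns `lag_ms`, `median_rho`,
#'   `pct_positive`); extrema annotations, when supplied, go to a JSON
#'   sidecar `<path>.json`.
#' @param extrema Optional `lag_extrema` annotation.
#' @return `path`, invisibly.
#' @export
write_lag_profile <- function(profile, path, extrema = NULL) {
  readr::write_csv(as_tibble(profile)[c("lag_ms", "median_rho", "pct_positive")], path)
  meta <- list(eta = attr(profile, "eta"),
               frame_rate = attr(profile, "frame_rate"),
               primary_max_lag_ms = attr(profile, "primary_max_lag_ms"))
  if (!is.null(extrema)) {
    meta$secondary_lag_avg_ms <- extrema$secondary_lag_avg_ms
    meta$has_secondary <- extrema$has_secondary
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
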