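#' Construct a modulation function
#'
#' A modulation function is a nonnegative per-frame-transition series
#' measuring how much a multichannel signal changes between successive
#' frames. Sample `k` (for source frames `k -> k + 1`) is assigned time
#' `k / frame_rate`.
#'
#' @param values Numeric series, one value per frame transition.
#' @param frame_rate Frame rate of the source signal, Hz.
#' @param kind `"articulatory"` or `"acoustic"`.
#' @param cutoff Low-pass cutoff applied (Hz), or `NA` if unsmoothed.
#' @return A tibble of class `modulation_function` with columns `frame`,
#'   `time`, `value`.
#' @export
modulation_function <- function(values, frame_rate,
                                kind = c("articulatory", "acoustic"),
                                cutoff = NA_real_) {
  kind <- match.arg(kind)
  out <- tibble(frame = seq_along(values),
                time = seq_along(values) / frame_rate,
                value = as.numeric(values))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "kind") <- kind
  attr(out, "cutoff") <- cutoff
  class(out) <- c("modulation_function", class(out))
  out
}

#' @export
print.modulation_function <- function(x, ...) {
  cat(sprintf("<modulation_function (%s): %d samples @ %.6g Hz, cutoff %s Hz>\n",
              attr(x, "kind"), nrow(x), attr(x, "frame_rate"),
              format(attr(x, "cutoff"))))
  NextMethod()
}

#' Sum of squared frame-to-frame differences
#'
#' The shared core of the articulatory and acoustic modulation functions:
#' for a frames-by-channels matrix, returns
#' `out[k] = sum_j (m[k + 1, j] - m[k, j])^2`, the summed squared velocity
#' across channels (frame-rate scaling omitted, as the frame rate is fixed).
#'
#' @param mat Numeric matrix or data frame, frames in rows.
#' @return Nonnegative numeric vector of length `nrow(mat) - 1`.
#' @export
frame_difference_energy <- function(mat) {
  m <- as.matrix(mat)
  if (nrow(m) < 2) {
    abort("Need at least 2 frames to compute frame differences.",
          class = "comod_insufficient_data")
  }
  d <- diff(m)
  rowSums(d * d)
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (zero net phase, effective order `2 * order`), the standard way of
#' smoothing physiological time series without shifting event times. Edges
#' are handled by odd-reflection padding with steady-state initial
#' conditions, so constant series pass through unchanged and boundary
#' transients do not contaminate nearby pulses.
#'
#' @param series Numeric series.
#' @param cutoff Cutoff frequency, Hz (must be below Nyquist).
#' @param frame_rate Sampling rate of the series, Hz.
#' @param order Filter order for each pass (default 4: nine filter
#'   coefficients per pass).
#' @return Filtered series, same length as the input.
#' @export
lowpass_zero_phase <- function(series, cutoff, frame_rate, order = 4) {
  x <- as.numeric(series)
  n <- length(x)
  if (cutoff >= frame_rate / 2) {
    abort("Cutoff must be below the Nyquist frequency.", class = "comod_parameter_error")
  }
  if (cutoff <= 0) abort("Cutoff must be positive.", class = "comod_parameter_error")
  min_len <- 3 * (2 * order + 1)
  if (n <= 2 * order + 1) {
    abort(sprintf("Series too short (%d) for zero-phase filtering.", n),
          class = "comod_insufficient_data")
  }
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  # One zero-state pass, offset so a constant input is in steady state.
  pass <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(b, a, v - v0)) + v0 * (sum(b) / sum(a))
  }
  p <- min(n - 1, min_len)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  y <- pass(xp)
  y <- rev(pass(rev(y)))
  y[(p + 1):(p + n)]
}

#' Articulatory modulation function (MBEAM)
#'
#' Computes the articulatory modulation function: the sum over all 14 marker
#' channels of squared frame-to-frame position differences -- with unit
#' masses, twice the kinetic energy of the articulator set -- then smooths it
#' with a zero-phase low-pass filter. Differencing acts as a high-pass, so
#' unsmoothed values are noisy; 12 Hz is the usual cutoff (marker kinematics
#' carry essentially no energy above ~10 Hz), with 25 Hz as a check
#' condition. Small post-smoothing negatives are clipped to zero, preserving
#' maxima locations.
#'
#' @param traj A [marker_trajectory()].
#' @param cutoff Smoothing cutoff in Hz, or `NA` to skip smoothing.
#' @return A [modulation_function()] of kind `"articulatory"`.
#' @export
compute_mbeam <- function(traj, cutoff = 12) {
  fr <- frame_rate(traj)
  raw <- frame_difference_energy(trajectory_matrix(traj))
  vals <- if (is.na(cutoff)) raw else pmax(0, lowpass_zero_phase(raw, cutoff, fr))
  modulation_function(vals, fr, kind = "articulatory", cutoff = cutoff)
}

#' Mel-cepstral front-end configuration
#'
#' Defaults follow the standard configuration for co-modulation analysis:
#' 25 ms analysis windows, hop equal to one articulatory frame (1/145.6 s),
#' preemphasis filter coefficients `(1, -0.97)`, 20 triangular mel filters
#' over 0--3700 Hz (the range well determined by anterior articulator
#' positions), and 13 cepstral coefficients. By default the coefficients are
#' c1--c13, excluding the frame-energy term c0 so that the features track
#' resonance structure rather than overall level; set `include_c0 = TRUE`
#' for the c0--c12 variant. Each coefficient series is smoothed with the
#' same zero-phase filter used for the articulatory channel.
#'
#' @param frame_rate Target feature frame rate, Hz.
#' @param window_length Analysis window, seconds.
#' @param preemphasis Preemphasis coefficient (high-pass `(1, -preemphasis)`).
#' @param n_filters Number of mel filterbank channels.
#' @param freq_range Filterbank frequency range `(low, high)`, Hz.
#' @param n_coeffs Number of cepstral coefficients retained.
#' @param include_c0 Include c0 (log frame energy proxy) as the first
#'   coefficient?
#' @param cutoff Per-coefficient smoothing cutoff, Hz (`NA` to skip).
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_rate = 145.6, window_length = 0.025,
                        preemphasis = 0.97, n_filters = 20,
                        freq_range = c(0, 3700), n_coeffs = 13,
                        include_c0 = FALSE, cutoff = 12) {
  if (n_coeffs > n_filters) {
    abort("n_coeffs must not exceed n_filters.", class = "comod_parameter_error")
  }
  structure(list(frame_rate = frame_rate, window_length = window_length,
                 preemphasis = preemphasis, n_filters = n_filters,
                 freq_range = freq_range, n_coeffs = n_coeffs,
                 include_c0 = include_c0, cutoff = cutoff),
            class = "mfcc_config")
}

#' Construct a feature matrix
#'
#' @param coeffs Frames x coefficients numeric matrix (or data frame).
#' @param frame_rate Feature frame rate, Hz.
#' @return A tibble of class `feature_matrix` with a `time` column and one
#'   column per coefficient (`c01`, `c02`, ...).
#' @export
feature_matrix <- function(coeffs, frame_rate) {
  m <- as.matrix(coeffs)
  if (any(!is.finite(m))) {
    abort("Feature matrix must be finite.", class = "comod_validation_error")
  }
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  out <- as_tibble(m)
  out <- tibble(time = (seq_len(nrow(out)) - 1) / frame_rate, !!!out)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("feature_matrix", class(out))
  out
}

# Coefficient matrix from a feature_matrix.
feature_coeffs <- function(features) {
  as.matrix(features[grep("^c[0-9]+$", names(features), value = TRUE)])
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_filters x (nfft/2 + 1).
mel_filterbank <- function(n_filters, nfft, sample_rate, freq_range) {
  mels <- seq(hz_to_mel(freq_range[1]), hz_to_mel(freq_range[2]),
              length.out = n_filters + 2)
  bins <- mel_to_hz(mels) / sample_rate * nfft
  freqs_bin <- 0:(nfft / 2)
  fb <- matrix(0, n_filters, nfft / 2 + 1)
  for (j in seq_len(n_filters)) {
    lo <- bins[j]; ctr <- bins[j + 1]; hi <- bins[j + 2]
    up <- (freqs_bin - lo) / (ctr - lo)
    down <- (hi - freqs_bin) / (hi - ctr)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-frequency cepstral coefficients, frame-locked to the articulatory rate
#'
#' Computes MFCCs from mono audio with the hop chosen as the integer sample
#' count best approximating one articulatory frame, so acoustic features are
#' (near-)synchronous with the marker frames; the realized frame rate
#' (`sample_rate / hop`) is recorded on the result. Pipeline: preemphasis,
#' Hamming-windowed frames, power spectrum, triangular mel filterbank,
#' log, orthonormal DCT-II, then per-coefficient zero-phase smoothing.
#'
#' @param audio An [audio_signal()].
#' @param cfg An [mfcc_config()].
#' @return A [feature_matrix()] of `cfg$n_coeffs` coefficients.
#' @export
compute_mfcc_features <- function(audio, cfg = mfcc_config()) {
  sr <- audio$sample_rate
  x <- audio$samples
  hop <- max(1L, as.integer(round(sr / cfg$frame_rate)))
  actual_rate <- sr / hop
  wl <- as.integer(round(cfg$window_length * sr))
  if (length(x) < wl + hop) {
    abort("Audio too short for two analysis windows.",
          class = "comod_insufficient_data")
  }
  x <- c(x[1], x[-1] - cfg$preemphasis * x[-length(x)])
  nfft <- 2^ceiling(log2(wl))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(wl - 1)) / (wl - 1))
  starts <- seq(1, length(x) - wl + 1, by = hop)
  fb <- mel_filterbank(cfg$n_filters, nfft, sr, cfg$freq_range)
  frames <- vapply(starts, function(s) {
    seg <- x[s:(s + wl - 1)] * win
    spec <- Mod(fft(c(seg, rep(0, nfft - wl))))[1:(nfft / 2 + 1)]^2
    as.vector(fb %*% spec)
  }, numeric(cfg$n_filters))
  # dynamic-range floor (80 dB below the frame's strongest filter) so that
  # empty filters do not inject log-of-leakage noise
  E <- t(frames)
  floor_e <- pmax(apply(E, 1, max) * 1e-8, .Machine$double.xmin)
  loge <- log(pmax(E, floor_e))
  # DCT-II with orthonormal scaling across the filterbank axis
  M <- cfg$n_filters
  idx <- if (cfg$include_c0) 0:(cfg$n_coeffs - 1) else seq_len(cfg$n_coeffs)
  dct <- vapply(idx, function(i) {
    sc <- if (i == 0) sqrt(1 / M) else sqrt(2 / M)
    sc * cos(pi * i * (seq_len(M) - 0.5) / M)
  }, numeric(M))
  cc <- loge %*% dct
  if (!is.na(cfg$cutoff)) {
    cc <- apply(cc, 2, lowpass_zero_phase, cutoff = cfg$cutoff,
                frame_rate = actual_rate)
  }
  feature_matrix(cc, actual_rate)
}

#' Acoustic modulation function (MFCC)
#'
#' The acoustic analogue of [compute_mbeam()]: the sum over cepstral
#' coefficients of squared frame-to-frame differences, smoothed with the
#' zero-phase low-pass filter and clipped at zero.
#'
#' @param features A [feature_matrix()].
#' @param cutoff Smoothing cutoff in Hz, or `NA` to skip smoothing.
#' @return A [modulation_function()] of kind `"acoustic"`.
#' @export
compute_mfcc_modulation <- function(features, cutoff = 12) {
  fr <- frame_rate(features)
  raw <- frame_difference_energy(feature_coeffs(features))
  vals <- if (is.na(cutoff)) raw else pmax(0, lowpass_zero_phase(raw, cutoff, fr))
  modulation_function(vals, fr, kind = "acoustic", cutoff = cutoff)
}

#' One-sided magnitude spectrum in dB relative to the peak
#'
#' Diagnostic used to choose the modulation smoothing cutoff: the spectrum
#' of a marker position series shows where kinematic energy runs out
#' (typically down by 60 dB at 10 Hz). The mean is removed and a Hann window
#' applied unless `window = "rectangular"`.
#'
#' @param series Numeric series.
#' @param frame_rate Sampling rate, Hz.
#' @param window `"hann"` (default) or `"rectangular"`.
#' @return A tibble with columns `frequency` (Hz) and `magnitude_db`
#'   (dB re: spectral peak).
#' @export
magnitude_spectrum <- function(series, frame_rate, window = c("hann", "rectangular")) {
  window <- match.arg(window)
  x <- as.numeric(series)
  if (length(x) == 0) abort("Empty series.", class = "comod_insufficient_data")
  x <- x - mean(x)
  n <- length(x)
  if (window == "hann" && n > 1) {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  }
  mag <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  freq <- (seq_len(n %/% 2 + 1) - 1) * frame_rate / n
  peak <- max(mag)
  db <- 20 * log10(pmax(mag, peak * 1e-300) / peak)
  tibble(frequency = freq, magnitude_db = db)
}

#' Write a modulation function (or feature matrix) as CSV with provenance
#'
#' The CSV holds `frame`/`time`/value columns; a JSON sidecar `<path>.json`
#' records frame rate, kind, and smoothing cutoff.
#'
#' @param x A [modulation_function()] or [feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_modulation <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  meta <- list(frame_rate = attr(x, "frame_rate"),
               kind = attr(x, "kind") %||% "features",
               cutoff = attr(x, "cutoff"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
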