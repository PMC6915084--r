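# Independent oracles and fixture builders used across the test files.

# Brute-force kernel-weighted Pearson correlation: explicit per-frame loop
# over the truncated support, weights renormalized over available samples.
brute_cma <- function(x, y, kernel, center = TRUE) {
  n <- length(x)
  L <- kernel$truncation_lag
  vapply(seq_len(n), function(k) {
    j <- max(1, k - L):min(n, k + L)
    w <- exp(-kernel$eta * abs(k - j))
    w <- w / sum(w)
    if (center) {
      mx <- sum(w * x[j]); my <- sum(w * y[j])
      sxy <- sum(w * (x[j] - mx) * (y[j] - my))
      sxx <- sum(w * (x[j] - mx)^2)
      syy <- sum(w * (y[j] - my)^2)
    } else {
      sxy <- sum(w * x[j] * y[j])
      sxx <- sum(w * x[j]^2)
      syy <- sum(w * y[j]^2)
    }
    sxy / sqrt(sxx * syy)
  }, numeric(1))
}

# Brute-force count of local maxima with the plateau-first rule: frame i is
# a maximum if the last nonzero difference before it is a rise and the next
# nonzero difference at/after it is a fall.
brute_local_max_count <- function(v) {
  d <- diff(v)
  count <- 0
  for (i in seq_along(d)) {
    if (d[i] > 0) {
      j <- i + 1
      while (j <= length(d) && d[j] == 0) j <- j + 1
      if (j <= length(d) && d[j] < 0) count <- count + 1
    }
  }
  count
}

# Exhaustive-enumeration two-sided sign test for small n: p is the
# probability, under fair signs, of a positive count at least as extreme
# (in either direction) as observed.
sign_test_enum <- function(k, n) {
  probs <- vapply(0:n, function(j) choose(n, j) / 2^n, numeric(1))
  sum(probs[abs(0:n - n / 2) >= abs(k - n / 2) - 1e-12])
}

# Construct a lag_profile object directly from vectors (for extrema and
# threshold tests on hand-built profiles).
make_profile <- function(lag_ms, median_rho, pct_positive = NULL,
                         frame_rate = 145.6, eta = 0.8) {
  out <- tibble::tibble(
    lag_frames = round(lag_ms * frame_rate / 1000),
    lag_ms = lag_ms,
    median_rho = median_rho,
    pct_positive = pct_positive %||% rep(100, length(lag_ms)))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "eta") <- eta
  attr(out, "primary_max_lag_ms") <- lag_ms[which.max(median_rho)]
  class(out) <- c("lag_profile", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One synthetic speaker's paired modulation functions (articulatory xb,
# acoustic xa), truncated to a common length.
gen_pair <- function(seed, n_syllables = 25, coupling = 0.8, noise_sd = 0.02,
                     syllable_rate = 4.9, duration_jitter = 0.15,
                     coda_counts = NULL, cutoff = 12) {
  cfg <- synth_config(n_speakers = 1, n_syllables = n_syllables,
                      syllable_rate = syllable_rate, coupling = coupling,
                      noise_sd = noise_sd, duration_jitter = duration_jitter,
                      seed = seed)
  specs <- withr::with_seed(seed, random_syllable_specs(n_syllables, cfg,
                                                        coda_counts = coda_counts))
  tr <- generate_trajectory(specs, cfg, seed = seed + 1L)
  ft <- generate_acoustic_stream(tr$trajectory, cfg, seed = seed + 2L)
  mb <- compute_mbeam(tr$trajectory, cutoff)
  mf <- compute_mfcc_modulation(ft, cutoff)
  n <- min(nrow(mb), nrow(mf))
  list(xb = mb$value[seq_len(n)], xa = mf$value[seq_len(n)],
       trajectory = tr$trajectory, segmentation = tr$segmentation,
       ground_truth = tr$ground_truth, features = ft,
       frame_rate = cfg$frame_rate)
}
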