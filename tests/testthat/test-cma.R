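test_that("kernel weights are normalized, symmetric, and shrink with eta", {
  for (eta in c(0.08, 0.2, 0.8)) {
    k <- kernel_weights(eta)
    expect_lt(abs(sum(k$weights) - 1), 1e-12)
    expect_equal(k$weights, rev(k$weights))
  }
  expect_lt(kernel_weights(0.8)$truncation_lag, kernel_weights(0.08)$truncation_lag)
  expect_error(kernel_weights(0), class = "comod_parameter_error")
  expect_error(kernel_weights(0.2, tolerance = 2), class = "comod_parameter_error")
})

test_that("windowed correlation is exact for linear relations and self-pairs", {
  set.seed(7)
  x <- rnorm(300)
  k <- kernel_weights(0.2)
  expect_true(all(abs(cma_correlate(x, 2 * x + 1, k)$rho - 1) < 1e-9))
  expect_true(all(abs(cma_correlate(x, -x, k)$rho + 1) < 1e-9))
  for (eta in c(0.08, 0.2, 0.8)) {
    expect_true(all(abs(cma_correlate(x, x, kernel_weights(eta))$rho - 1) < 1e-9))
  }
  # constant series: zero local variance -> undefined
  expect_true(all(is.na(cma_correlate(rep(2, 50), rnorm(50), k)$rho)))
  expect_error(cma_correlate(rnorm(10), rnorm(11), k),
               class = "comod_parameter_error")
})

test_that("windowed correlation matches the brute-force weighted-Pearson oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    eta <- sample(c(0.08, 0.2, 0.8), 1)
    x <- rnorm(n); y <- rnorm(n)
    k <- kernel_weights(eta)
    got <- cma_correlate(x, y, k)$rho
    want <- pmin(1, pmax(-1, brute_cma(x, y, k)))
    expect_lt(max(abs(got - want)), 1e-10)
    # uncentred variant against its own oracle
    got_u <- cma_correlate(x, y, k, center = FALSE)$rho
    want_u <- pmin(1, pmax(-1, brute_cma(x, y, k, center = FALSE)))
    expect_lt(max(abs(got_u - want_u)), 1e-10)
  }
})

test_that("median correlation is taken over defined samples only", {
  expect_equal(median_correlation(c(1, 1, 1)), 1)
  expect_equal(median_correlation(c(-1, 0, 1)), 0)
  expect_equal(median_correlation(c(NA, 0.4, 0.6, NA)), 0.5)
  expect_error(median_correlation(c(NA_real_, NA_real_)),
               class = "comod_insufficient_data")
})

test_that("lag sweeps recover planted shifts and are symmetric for self-pairs", {
  fr <- 145.6
  set.seed(12)
  base <- lowpass_zero_phase(rnorm(600), 10, fr)
  k <- kernel_weights(0.8)
  # y = x delayed by 3 frames (y[t] = x[t - 3]); positive lag delays x
  y <- c(rep(base[1], 3), base[seq_len(597)])
  prof <- lag_sweep(base, y, k, 100, fr)
  expect_equal(prof$lag_frames[which.max(prof$median_rho)], 3L)

  auto <- lag_sweep(base, base, k, 100, fr)
  expect_lt(max(abs(auto$median_rho - rev(auto$median_rho))), 1e-9)
  expect_equal(auto$median_rho[auto$lag_frames == 0], 1, tolerance = 1e-9)

  expect_error(lag_sweep(rnorm(40), rnorm(40), k, 200, fr),
               class = "comod_parameter_error")
})

test_that("lag extrema find secondary maxima referenced to the primary maximum", {
  # cosine-shaped profile with a 130 ms period, on a frame-aligned grid
  lag <- (-29:29) * 1000 / 145.6
  prof <- make_profile(lag, 0.5 * cos(2 * pi * lag / 130))
  ex <- find_lag_extrema(prof, 170)
  expect_true(ex$has_secondary)
  expect_lt(abs(ex$secondary_lag_avg_ms - 130), 1000 / 145.6)

  # monotone decay: no minima, no secondary structure
  decay <- make_profile(lag, exp(-abs(lag) / 80))
  exd <- find_lag_extrema(decay, 170)
  expect_false(exd$has_secondary)
  expect_true(is.na(exd$secondary_lag_avg_ms))

  # primary maximum off zero: secondary lags referenced to it
  frame_ms <- 1000 / 145.6
  v <- 0.5 * cos(2 * pi * (lag - frame_ms) / 130)
  exo <- find_lag_extrema(make_profile(lag, v), 170)
  expect_equal(exo$primary_max_lag_ms, frame_ms, tolerance = 1e-9)
  expect_lt(abs(exo$secondary_lag_avg_ms - 130), frame_ms)

  expect_error(find_lag_extrema(make_profile(seq(-100, 100, 10), rnorm(21)), 170),
               class = "comod_parameter_error")
})

test_that("positive threshold lag measures the 50% crossing distance", {
  lag <- seq(-200, 200, by = 5)
  p <- ifelse(abs(lag) < 40, 100, 0)
  prof <- make_profile(lag, exp(-(lag / 100)^2), pct_positive = p)
  th <- positive_threshold_lag(prof)
  expect_equal(th$threshold_ms, 40)
  expect_false(th$unbounded)

  all_pos <- make_profile(lag, exp(-(lag / 100)^2))
  th2 <- positive_threshold_lag(all_pos)
  expect_true(th2$unbounded)
  expect_true(is.na(th2$threshold_ms))
})

test_that("the eta-to-cutoff map matches its anchors and the small-eta closed form", {
  cuts <- eta_to_cutoff(c(0.8, 0.2, 0.08), 145.6)
  expect_lt(abs(cuts[1] - 12.4) / 12.4, 0.10)
  expect_lt(abs(cuts[2] / cuts[3] - 2.5) / 2.5, 0.02)
  # small-eta closed form: omega = eta * sqrt(sqrt(2) - 1) rad/frame
  expect_equal(eta_to_cutoff(0.01, 145.6),
               0.01 * sqrt(sqrt(2) - 1) / (2 * pi) * 145.6,
               tolerance = 1e-3)
  # monotone in eta
  grid <- eta_to_cutoff(c(0.05, 0.1, 0.3, 0.6, 1.2), 145.6)
  expect_true(all(diff(grid) > 0))
})
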