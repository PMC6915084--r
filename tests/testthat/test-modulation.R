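test_that("frame difference energy matches hand values and a brute-force loop", {
  expect_equal(frame_difference_energy(matrix(1, 5, 3)), rep(0, 4))
  expect_equal(frame_difference_energy(rbind(c(0, 0), c(3, 4))), 25)

  set.seed(21)
  m <- matrix(rnorm(10 * 14), 10, 14)
  brute <- vapply(1:9, function(k) {
    acc <- 0
    for (j in 1:14) acc <- acc + (m[k + 1, j] - m[k, j])^2
    acc
  }, numeric(1))
  expect_equal(frame_difference_energy(m), brute, tolerance = 1e-12)

  # homogeneity: doubling positions quadruples the energy
  expect_equal(frame_difference_energy(2 * m), 4 * frame_difference_energy(m))

  expect_error(frame_difference_energy(matrix(0, 1, 14)),
               class = "comod_insufficient_data")
})

test_that("zero-phase low-pass passes DC and low tones, attenuates the stopband", {
  fr <- 145.6
  expect_lt(max(abs(lowpass_zero_phase(rep(3.7, 300), 12, fr) - 3.7)), 1e-9)

  t <- (0:999) / fr
  x2 <- sin(2 * pi * 2 * t)
  y2 <- lowpass_zero_phase(x2, 12, fr)
  interior <- 100:900
  expect_lt(abs(max(y2[interior]) - max(x2[interior])) / max(x2[interior]), 0.01)
  # zero phase: peak times unshifted within one frame
  px <- interior[which.max(x2[interior])]
  expect_lte(abs(interior[which.max(y2[interior])] - px), 1)

  x40 <- sin(2 * pi * 40 * t)
  y40 <- lowpass_zero_phase(x40, 12, fr)
  expect_lt(sqrt(mean(y40[interior]^2)) / sqrt(mean(x40[interior]^2)), 0.05)

  expect_error(lowpass_zero_phase(x2, 80, fr), class = "comod_parameter_error")
  expect_error(lowpass_zero_phase(rnorm(5), 12, fr),
               class = "comod_insufficient_data")
})

test_that("articulatory modulation is additive over channels and twice the kinetic energy", {
  fr <- 145.6
  static <- marker_trajectory(matrix(2, 50, 14), fr)
  expect_equal(compute_mbeam(static)$value, rep(0, 49))

  # single moving marker: modulation equals that channel's squared velocity
  pos <- matrix(5, 200, 14)
  pos[, 3] <- sin(2 * pi * 3 * (0:199) / fr)
  traj <- marker_trajectory(pos, fr)
  single <- compute_mbeam(traj, cutoff = 12)
  chan_only <- lowpass_zero_phase(diff(pos[, 3])^2, 12, fr)
  expect_equal(single$value, pmax(0, chan_only), tolerance = 1e-12)

  # rigid translation invariance
  shifted <- marker_trajectory(sweep(pos, 2, rnorm(14), "+"), fr)
  expect_equal(compute_mbeam(shifted)$value, single$value, tolerance = 1e-10)

  # unsmoothed modulation = 2 * kinetic energy with unit masses
  set.seed(3)
  m <- matrix(rnorm(30 * 14), 30, 14)
  raw <- compute_mbeam(marker_trajectory(m, fr), cutoff = NA)
  ke <- vapply(1:29, function(k) 0.5 * sum((m[k + 1, ] - m[k, ])^2), numeric(1))
  expect_equal(raw$value, 2 * ke, tolerance = 1e-12)
})

test_that("mel-cepstral features are stationary for steady inputs and track changes", {
  sr <- 16000
  hop <- round(sr / 145.6)
  get_cc <- function(f) as.matrix(f[grep("^c[0-9]+$", names(f))])

  # near-silence: coefficient variance tiny compared to structured audio
  set.seed(1)
  silence <- audio_signal(rnorm(sr, 0, 1e-6), sr)
  fs <- compute_mfcc_features(silence, mfcc_config())
  mk_vowel <- function(f1, f2, dur) {
    tt <- (0:(dur * sr - 1)) / sr
    0.5 * sin(2 * pi * f1 * tt) + 0.3 * sin(2 * pi * f2 * tt)
  }
  two_vowels <- audio_signal(c(mk_vowel(300, 2300, 0.5), mk_vowel(700, 1100, 0.5)), sr)
  fv <- compute_mfcc_features(two_vowels, mfcc_config())
  expect_lt(sum(apply(get_cc(fs), 2, var)), 0.05 * sum(apply(get_cc(fv), 2, var)))

  # steady tone phase-locked to the hop: constant interior coefficients
  f0 <- round(500 / (sr / hop)) * (sr / hop)
  tone <- audio_signal(sin(2 * pi * f0 * (0:(2 * sr - 1)) / sr), sr)
  ftn <- compute_mfcc_features(tone, mfcc_config(cutoff = NA))
  cc <- get_cc(ftn)
  interior <- cc[20:(nrow(cc) - 20), ]
  expect_lt(max(apply(interior, 2, sd)), 1e-8)

  # vowel junction located within +/- 2 frames
  chg <- rowSums(abs(diff(get_cc(fv))))
  expect_lte(abs(which.max(chg) - 0.5 * frame_rate(fv)), 2)

  expect_equal(ncol(get_cc(fv)), 13)
  expect_error(compute_mfcc_features(audio_signal(rnorm(100), sr), mfcc_config()),
               class = "comod_insufficient_data")
})

test_that("acoustic modulation has the unit-step and offset-invariance properties", {
  fr <- 145.6
  const <- feature_matrix(matrix(1.5, 40, 13), fr)
  expect_equal(compute_mfcc_modulation(const, cutoff = NA)$value, rep(0, 39))

  two <- matrix(0, 2, 13); two[2, 5] <- 1
  expect_equal(compute_mfcc_modulation(feature_matrix(two, fr), cutoff = NA)$value, 1)

  set.seed(8)
  co <- matrix(rnorm(60 * 13), 60, 13)
  base <- compute_mfcc_modulation(feature_matrix(co, fr))
  co2 <- co; co2[, 4] <- co2[, 4] + 7.7
  expect_equal(compute_mfcc_modulation(feature_matrix(co2, fr))$value,
               base$value, tolerance = 1e-10)
})

test_that("magnitude spectrum localizes tones and resolves a -60 dB partial", {
  fr <- 145.6
  n <- 2048
  t <- (0:(n - 1)) / fr
  sp <- magnitude_spectrum(sin(2 * pi * 5 * t), fr)
  expect_lt(abs(sp$frequency[which.max(sp$magnitude_db)] - 5), fr / n * 1.5)

  set.seed(99)
  x <- rnorm(512)
  expect_identical(magnitude_spectrum(x, fr), magnitude_spectrum(x, fr))

  # bin-centred two-tone signal, rectangular window: exact -60 dB partial
  n <- 4096
  f1 <- 200 * fr / n; f2 <- 400 * fr / n
  tt <- (0:(n - 1)) / fr
  two <- sin(2 * pi * f1 * tt) + 1e-3 * sin(2 * pi * f2 * tt)
  sp2 <- magnitude_spectrum(two, fr, window = "rectangular")
  expect_equal(sp2$magnitude_db[401], -60, tolerance = 0.01)

  expect_error(magnitude_spectrum(numeric(0), fr),
               class = "comod_insufficient_data")
})
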