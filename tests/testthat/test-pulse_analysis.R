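test_that("pulse detection finds maxima, honours plateaus, and skips endpoints", {
  fr <- 145.6
  expect_equal(nrow(detect_pulses(rep(1, 50), frame_rate = fr)), 0)

  bump <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50)[-1])
  p <- detect_pulses(bump, frame_rate = fr)
  expect_equal(p$frame, 50)
  expect_equal(p$time, 50 / fr)

  # raised 5 Hz sinusoid: pulses 200 ms apart within one frame
  t <- (0:999) / fr
  p5 <- detect_pulses(1 + sin(2 * pi * 5 * t), frame_rate = fr)
  expect_true(all(abs(diff(p5$time) - 0.2) <= 1 / fr + 1e-9))

  # plateau: first frame of the flat top is the maximum
  plat <- c(0, 1, 2, 2, 2, 1, 0)
  expect_equal(detect_pulses(plat, frame_rate = fr)$frame, 3)

  # monotone series: no pulses, and no endpoint artifacts
  expect_equal(nrow(detect_pulses(seq_len(100), frame_rate = fr)), 0)
  expect_error(detect_pulses(c(1, 2), frame_rate = fr),
               class = "comod_insufficient_data")
})

test_that("pulse counts equal the brute-force local-maxima count on random smooth series", {
  fr <- 145.6
  for (i in 1:25) {
    set.seed(500 + i)
    v <- lowpass_zero_phase(rnorm(300), 8, fr)
    expect_equal(nrow(detect_pulses(v, frame_rate = fr)),
                 brute_local_max_count(v))
  }
})

test_that("inter-pulse summaries use the reciprocal of the mean interval", {
  s <- interpulse_summary(c(0.1, 0.3, 0.5))
  expect_equal(s$mean_interval, 0.2)
  expect_equal(s$sd_interval, 0)
  expect_equal(s$pulse_frequency, 5)

  s2 <- interpulse_summary(c(0.1, 0.2, 0.4))
  expect_equal(s2$mean_interval, 0.15)
  expect_equal(s2$pulse_frequency, 1 / 0.15)

  s3 <- interpulse_summary(0.4)
  expect_true(is.na(s3$pulse_frequency))
  expect_equal(s3$n_pulses, 1)
})

test_that("coda classification counts post-vocalic consonants in ARPAbet", {
  expect_equal(classify_coda(c("HH", "IY")), "open")
  expect_equal(classify_coda(c("W", "AH", "N", "S")), "multi_coda")
  expect_equal(classify_coda(c("B", "ER", "D")), "one_coda")
  # stress digits ignored
  expect_equal(classify_coda(c("B", "ER1", "D")), "one_coda")
  # no vowel: unclassifiable
  expect_true(is.na(classify_coda(c("S", "T"))))
})

test_that("syllable tallies use half-open windows, exclude pauses, and balance totals", {
  seg <- syllable_segmentation(
    tibble::tibble(start = c(0, 0.2), end = c(0.2, 0.4),
                   label = c("a", "b"), coda_class = c("open", "one_coda")))
  tal <- tally_pulses_by_syllable(c(0.1, 0.35), seg)
  expect_equal(tal$per_syllable$n_pulses, c(1L, 1L))

  # boundary pulse goes to the second (half-open) interval
  tal2 <- tally_pulses_by_syllable(0.2, seg)
  expect_equal(tal2$per_syllable$n_pulses, c(0L, 1L))

  # empty train
  tal3 <- tally_pulses_by_syllable(numeric(0), seg)
  expect_equal(tal3$per_syllable$n_pulses, c(0L, 0L))
  expect_equal(tal3$class_means$mean_pulses, c(0, 0, 0))

  # pulse in a pause: silently excluded; stray pulse: warning
  segp <- syllable_segmentation(
    tibble::tibble(start = c(0, 0.6), end = c(0.2, 0.8),
                   label = c("a", "b"), coda_class = c("open", "open")),
    utterance_span = c(0, 0.8),
    pauses = tibble::tibble(start = 0.2, end = 0.6))
  expect_silent(tally_pulses_by_syllable(c(0.1, 0.4), segp))
  expect_warning(tally_pulses_by_syllable(c(0.1, 0.9), segp), "excluded")

  # tally balance: sum over classes of n * mean equals pulses assigned
  set.seed(44)
  pulses <- sort(runif(30, 0, 0.4))
  tal4 <- tally_pulses_by_syllable(pulses, seg)
  with_cls <- tal4$class_means
  expect_equal(sum(with_cls$n_syllables * with_cls$mean_pulses),
               sum(tal4$per_syllable$n_pulses))
})

test_that("syllable counting handles the disyllabic lexicon", {
  sentence <- c("Once", "he", "thought", "he", "saw", "a", "bird,", "but",
                "it", "was", "just", "a", "large", "leaf", "that", "had",
                "failed", "to", "drop", "to", "the", "ground", "during",
                "the", "winter.")
  expect_equal(count_syllables(sentence), 27L)
  expect_equal(count_syllables(character(0)), 0L)
  expect_equal(count_syllables("winter"), 2L)
})

test_that("syllable rate comes from pause-free speech time", {
  r <- estimate_syllable_rate(6.0, 0.6, 27)
  expect_equal(r$mean_syllable_duration, 0.2)
  expect_equal(r$syllable_rate, 5)
  expect_equal(estimate_syllable_rate(27, numeric(0), 27)$syllable_rate, 1)
  expect_error(estimate_syllable_rate(1, 1.2, 10), class = "comod_domain_error")
  expect_error(estimate_syllable_rate(1, 0, 0), class = "comod_domain_error")
})

test_that("smoothing more aggressively never adds pulses (12 vs 25 Hz)", {
  # statistical property over seeded synthetic utterances
  worse <- 0
  total12 <- 0; total25 <- 0
  for (i in 1:50) {
    cfg <- synth_config(n_speakers = 1, n_syllables = 15, seed = 300 + i)
    specs <- withr::with_seed(300 + i, random_syllable_specs(15, cfg))
    tr <- generate_trajectory(specs, cfg, seed = 400 + i)
    c12 <- nrow(detect_pulses(compute_mbeam(tr$trajectory, 12)))
    c25 <- nrow(detect_pulses(compute_mbeam(tr$trajectory, 25)))
    if (c12 > c25) worse <- worse + 1
    total12 <- total12 + c12; total25 <- total25 + c25
  }
  expect_lte(worse, 5)
  expect_lt(total12, total25)
})
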