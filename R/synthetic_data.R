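#' Configuration for the synthetic paired-corpus generator
#'
#' The generator emulates the structure of microbeam-style recordings:
#' 14-channel smooth marker kinematics at 145.6 Hz driven by syllable
#' gestures, paired with a causally coupled 13-channel acoustic feature
#' stream at the same frame rate. Defaults mirror the read-sentence corpus
#' the method targets: 23 speakers, a median syllable rate near 4.9 Hz, and
#' utterances of a few dozen syllables.
#'
#' @param n_speakers Number of synthetic speakers.
#' @param n_syllables Syllables per utterance.
#' @param syllable_rate Mean syllable rate, Hz.
#' @param frame_rate Frame rate, Hz.
#' @param noise_sd Measurement noise SD per articulatory channel (position
#'   units; gesture targets have unit-scale spread).
#' @param n_acoustic Number of acoustic feature channels.
#' @param coupling Articulatory-to-acoustic coupling strength in `[0, 1]`
#'   (0 = independent streams, 1 = fully articulator-driven).
#' @param rate_jitter Relative jitter of the per-speaker syllable rate.
#' @param duration_jitter Relative jitter of individual syllable durations
#'   (0 gives strictly periodic syllables).
#' @param coda_probs Probabilities of open / one-coda / multi-coda syllables.
#' @param gesture_tau Gesture time constant, seconds (velocity of a
#'   critically damped transition peaks `tau` after gesture onset).
#' @param seed Base seed; all randomness derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_speakers = 23, n_syllables = 30, syllable_rate = 4.9,
                         frame_rate = 145.6, noise_sd = 0.02, n_acoustic = 13,
                         coupling = 0.8, rate_jitter = 0.1,
                         duration_jitter = 0.15,
                         coda_probs = c(open = 0.45, one_coda = 0.35, multi_coda = 0.2),
                         gesture_tau = 0.04, seed = 1L) {
  if (syllable_rate <= 0 || frame_rate <= 0) {
    abort("Rates must be positive.", class = "comod_config_error")
  }
  if (coupling < 0 || coupling > 1) {
    abort("coupling must be in [0, 1].", class = "comod_config_error")
  }
  structure(list(n_speakers = n_speakers, n_syllables = n_syllables,
                 syllable_rate = syllable_rate, frame_rate = frame_rate,
                 noise_sd = noise_sd, n_acoustic = n_acoustic,
                 coupling = coupling, rate_jitter = rate_jitter,
                 duration_jitter = duration_jitter,
                 coda_probs = coda_probs / sum(coda_probs),
                 gesture_tau = gesture_tau, seed = as.integer(seed)),
            class = "synth_config")
}

# phone inventories for synthetic labels
synth_consonants <- c("B", "D", "G", "K", "L", "M", "N", "P", "R", "S", "T", "Z")
synth_vowels <- c("AA", "AE", "EH", "IY", "OW", "UW")

#' Draw a random syllable plan
#'
#' Builds the syllable specification table the trajectory generator
#' consumes: each row is a syllable with an onset/coda consonant count, a
#' duration, and a phone-string label consistent with its structure (so
#' [classify_coda()] recovers the coda class). Durations scale with
#' structural complexity and are normalized so the mean syllable rate
#' matches `cfg$syllable_rate` in expectation.
#'
#' @param n Number of syllables.
#' @param cfg A [synth_config()].
#' @param coda_counts Optional integer vector of coda counts (overrides the
#'   random draw; e.g. `rep(0, n)` for a CV-only utterance).
#' @return A tibble of class `syllable_spec`: `label`, `n_onset`, `n_coda`,
#'   `duration`, `stress`.
#' @export
random_syllable_specs <- function(n, cfg = synth_config(), coda_counts = NULL) {
  if (n < 1) abort("Need at least one syllable.", class = "comod_config_error")
  if (is.null(coda_counts)) {
    coda_counts <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = cfg$coda_probs)
  }
  n_onset <- rep(1L, n)
  # complexity-scaled durations, normalized so the realized mean syllable
  # duration is 1 / syllable_rate
  scale <- 1 + 0.45 * coda_counts
  base <- (1 / cfg$syllable_rate) / mean(scale)
  jit <- if (cfg$duration_jitter > 0) {
    exp(rnorm(n, 0, cfg$duration_jitter)) } else rep(1, n)
  duration <- base * scale * jit
  label <- vapply(seq_len(n), function(i) {
    phones <- c(sample(synth_consonants, n_onset[i]),
                sample(synth_vowels, 1),
                if (coda_counts[i] > 0) sample(synth_consonants, coda_counts[i]))
    paste(phones, collapse = " ")
  }, character(1))
  out <- tibble(label = label, n_onset = n_onset, n_coda = as.integer(coda_counts),
                duration = duration, stress = 1)
  class(out) <- c("syllable_spec", class(out))
  out
}

#' Generate a synthetic marker trajectory with known ground truth
#'
#' Each syllable contributes one onset-release gesture plus one gesture per
#' coda consonant. A gesture moves a random subset of the 14 channels toward
#' new targets through a critically damped second-order transition (time
#' constant `cfg$gesture_tau`), producing smooth, low-frequency kinematics;
#' the velocity maximum of each gesture (onset + tau) is recorded as a
#' planted pulse time. White measurement noise of SD `cfg$noise_sd` is
#' added per channel.
#'
#' @param specs A syllable plan from [random_syllable_specs()].
#' @param cfg A [synth_config()].
#' @param seed Seed for this utterance (defaults to `cfg$seed`).
#' @return A list: `trajectory` ([marker_trajectory()]), `segmentation`
#'   ([syllable_segmentation()]), `ground_truth` (list with `pulse_times`,
#'   `pulses_per_syllable`, `syllables`, `seed`).
#' @export
generate_trajectory <- function(specs, cfg = synth_config(), seed = NULL) {
  if (nrow(specs) == 0 || sum(specs$duration) <= 0) {
    abort("Syllable specs must have positive total duration.",
          class = "comod_config_error")
  }
  seed <- seed %||% cfg$seed
  fr <- cfg$frame_rate
  lead <- 0.3
  total <- lead * 2 + sum(specs$duration)
  n_frames <- ceiling(total * fr) + 1
  starts <- lead + cumsum(c(0, specs$duration[-nrow(specs)]))
  ends <- starts + specs$duration

  local_seed(seed, {
    # gesture schedule: one onset-release gesture early in the syllable,
    # plus evenly spread coda gestures in its second half
    gest <- purrr::map(seq_len(nrow(specs)), function(i) {
      on <- starts[i] + 0.08 * specs$duration[i]
      codas <- if (specs$n_coda[i] > 0) {
        # coda gestures close the syllable: each coda consonant takes a
        # roughly fixed slot, the last peaking just before the end
        nc <- specs$n_coda[i]
        peaks <- ends[i] - 0.05 - 0.085 * (nc - seq_len(nc))
        peaks <- pmax(peaks, starts[i] + 0.35 * specs$duration[i])
        peaks - cfg$gesture_tau
      } else numeric(0)
      c(on, codas)
    })
    gest_times <- sort(unlist(gest))
    per_syll <- vapply(gest, length, integer(1))

    # piecewise-constant channel targets, then critically damped smoothing
    posture <- rnorm(14, 0, 1)
    targets <- matrix(rep(posture, each = n_frames), n_frames, 14)
    for (g in gest_times) {
      k0 <- max(1L, floor(g * fr) + 1L)
      chans <- sample(14, sample(4:8, 1))
      shift <- rnorm(length(chans), 0, 0.7)
      for (ci in seq_along(chans)) {
        targets[k0:n_frames, chans[ci]] <- targets[k0, chans[ci]] + shift[ci]
      }
    }
    a <- exp(-1 / (fr * cfg$gesture_tau))
    smooth2 <- function(v) {
      y <- stats::filter(v * (1 - a), a, method = "recursive", init = v[1])
      as.numeric(stats::filter(as.numeric(y) * (1 - a), a, method = "recursive",
                               init = v[1]))
    }
    pos <- apply(targets, 2, smooth2)
    pos <- pos + matrix(rnorm(length(pos), 0, cfg$noise_sd), nrow(pos))
    colnames(pos) <- mb_channels()

    seg <- syllable_segmentation(
      tibble(start = starts, end = ends, label = specs$label),
      utterance_span = c(lead, lead + sum(specs$duration)))
    list(trajectory = marker_trajectory(pos, fr),
         segmentation = seg,
         ground_truth = list(pulse_times = gest_times + cfg$gesture_tau,
                             pulses_per_syllable = 1L + specs$n_coda,
                             syllables = seg,
                             seed = seed))
  })
}

# independent gesture-structured stream: critically damped transitions at
# its own random times, standardized; statistically like an articulatory
# channel but with no timing relation to the trajectory
gesture_stream <- function(n, fr, rate, tau) {
  a <- exp(-1 / (fr * tau))
  n_gest <- max(1L, stats::rpois(1, rate * n / fr))
  ks <- sort(sample.int(n, min(n, n_gest)))
  lev <- cumsum(c(rnorm(1), rnorm(length(ks), 0, 0.7)))
  targ <- lev[findInterval(seq_len(n), ks) + 1L]
  y <- as.numeric(stats::filter(targ * (1 - a), a, method = "recursive", init = targ[1]))
  y <- as.numeric(stats::filter(y * (1 - a), a, method = "recursive", init = targ[1]))
  y / max(sd(y), .Machine$double.eps)
}

#' Generate a causally coupled acoustic feature stream
#'
#' Produces `cfg$n_acoustic` feature channels frame-synchronously from a
#' marker trajectory: a fixed random smooth nonlinear mixture
#' (tanh-of-linear, mixing weights drawn from the seed) of the standardized
#' articulatory channels, weighted by the coupling strength, plus
#' independent smooth channels standing in for articulatory dimensions the
#' markers do not capture (velum, glottis, pharynx), plus white noise. The
#' map is strictly zero-lag: frame `k` of the output depends only on frame
#' `k` of the input.
#'
#' @param traj A [marker_trajectory()].
#' @param cfg A [synth_config()].
#' @param seed Seed for the mixing map and noise (defaults to `cfg$seed`).
#' @return A [feature_matrix()].
#' @export
generate_acoustic_stream <- function(traj, cfg = synth_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  m <- trajectory_matrix(traj)
  n <- nrow(m)
  z <- scale(m)
  z[!is.finite(z)] <- 0
  local_seed(seed, {
    W <- matrix(rnorm(cfg$n_acoustic * 14, 0, 1 / sqrt(14)), cfg$n_acoustic, 14)
    coupled <- tanh(z %*% t(W))
    coupled <- apply(coupled, 2, function(v) v / max(sd(v), .Machine$double.eps))
    # unmodeled articulatory dimensions (velum, glottis, pharynx stand-ins):
    # gesture-structured but independently timed, at roughly the utterance's
    # overall gesture rate
    hidden_rate <- cfg$syllable_rate * 1.4
    indep <- vapply(seq_len(cfg$n_acoustic), function(j) {
      gesture_stream(n, frame_rate(traj), hidden_rate, cfg$gesture_tau)
    }, numeric(n))
    # correlation-preserving mixture of standardized components, so that
    # `coupling` is the feature-space correlation with the driven part
    f <- cfg$coupling * coupled + sqrt(1 - cfg$coupling^2) * indep +
      matrix(rnorm(n * cfg$n_acoustic, 0, cfg$noise_sd), n)
    feature_matrix(f, frame_rate(traj))
  })
}

#' Generate a synthetic multi-speaker corpus
#'
#' Draws `cfg$n_speakers` utterances with per-speaker jittered syllable
#' rates and independent mixing maps, each comprising a marker trajectory,
#' a coupled acoustic feature stream, a syllable segmentation, and the
#' planted ground truth. All randomness derives from `cfg$seed` through a
#' per-speaker seed-splitting scheme, so the corpus is reproducible
#' speaker-by-speaker.
#'
#' @param cfg A [synth_config()].
#' @param coda_counts Optional fixed coda-count vector passed to
#'   [random_syllable_specs()] (e.g. all zeros for a CV-only corpus).
#' @return A list of speakers; each is a list with `speaker`, `trajectory`,
#'   `features`, `segmentation`, `ground_truth`.
#' @export
generate_corpus <- function(cfg = synth_config(), coda_counts = NULL) {
  if (cfg$n_speakers < 1) abort("Need at least one speaker.", class = "comod_config_error")
  purrr::map(seq_len(cfg$n_speakers), function(i) {
    s_spec <- split_seed(cfg$seed, 3L * i)
    s_traj <- split_seed(cfg$seed, 3L * i + 1L)
    s_ac <- split_seed(cfg$seed, 3L * i + 2L)
    spk_cfg <- cfg
    spk_cfg$syllable_rate <- local_seed(s_spec,
      cfg$syllable_rate * (1 + runif(1, -cfg$rate_jitter, cfg$rate_jitter)))
    specs <- local_seed(s_spec + 1L,
      random_syllable_specs(cfg$n_syllables, spk_cfg, coda_counts = coda_counts))
    tr <- generate_trajectory(specs, spk_cfg, seed = s_traj)
    feats <- generate_acoustic_stream(tr$trajectory, spk_cfg, seed = s_ac)
    list(speaker = sprintf("S%02d", i),
         trajectory = tr$trajectory,
         features = feats,
         segmentation = tr$segmentation,
         ground_truth = tr$ground_truth)
  })
}

#' Render a feature stream as audible amplitude-modulated tones
#'
#' Optional audio rendering used to exercise the real mel-cepstral
#' front-end: each feature channel amplitude-modulates a fixed tone
#' (log-spaced 200--3400 Hz), with channel values rescaled to `[0, 1]`.
#' This is a synthetic stand-in for real speech audio, not a vocal-tract
#' synthesis.
#'
#' @param features A [feature_matrix()].
#' @param sample_rate Output audio sampling rate, Hz.
#' @return An [audio_signal()].
#' @export
render_audio_stream <- function(features, sample_rate = 16000) {
  f <- feature_coeffs(features)
  fr <- frame_rate(features)
  n_samp <- ceiling(nrow(f) / fr * sample_rate)
  t_aud <- (seq_len(n_samp) - 1) / sample_rate
  t_frm <- (seq_len(nrow(f)) - 1) / fr
  tones <- exp(seq(log(200), log(3400), length.out = ncol(f)))
  x <- numeric(n_samp)
  for (j in seq_len(ncol(f))) {
    rng <- range(f[, j])
    amp01 <- if (diff(rng) > 0) (f[, j] - rng[1]) / diff(rng) else rep(0, nrow(f))
    amp <- stats::approx(t_frm, amp01, xout = t_aud, rule = 2)$y
    x <- x + amp * sin(2 * pi * tones[j] * t_aud)
  }
  audio_signal(0.8 * x / max(abs(x)), sample_rate)
}
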