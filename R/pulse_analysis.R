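#' Detect modulation pulses
#'
#' Modulation pulses are the successive local maxima of a modulation
#' function, found at sign changes (+ to -) of its first difference, i.e.
#' zero crossings of the derivative. Plateaus (runs of exactly zero first
#' difference) contribute their first frame as the maximum; series endpoints
#' are never pulses. A constant series yields an empty train.
#'
#' @param modfn A [modulation_function()] (or numeric series, in which case
#'   `frame_rate` must be supplied).
#' @param frame_rate Frame rate, Hz; taken from `modfn` when omitted.
#' @return A tibble of class `pulse_train` with columns `frame`, `time`, and
#'   `value` (height of the maximum); attribute `kind` carries the source
#'   kind.
#' @export
detect_pulses <- function(modfn, frame_rate = NULL) {
  if (inherits(modfn, "modulation_function")) {
    v <- modfn$value
    frame_rate <- frame_rate %||% attr(modfn, "frame_rate")
    kind <- attr(modfn, "kind")
  } else {
    v <- as.numeric(modfn)
    kind <- NA_character_
  }
  if (is.null(frame_rate)) abort("frame_rate required.", class = "comod_config_error")
  if (length(v) < 3) {
    abort("Need at least 3 samples to detect pulses.", class = "comod_insufficient_data")
  }
  d <- diff(v)
  s <- sign(d)
  # a maximum is at frame i+1 when d[i] > 0 and the next nonzero first
  # difference is negative; zeros in between are a plateau, whose first
  # frame (i+1) is taken as the maximum
  peaks <- integer(0)
  for (i in which(s > 0)) {
    j <- i + 1
    while (j <= length(s) && s[j] == 0) j <- j + 1
    if (j <= length(s) && s[j] < 0) peaks <- c(peaks, i + 1L)
  }
  out <- tibble(frame = peaks,
                time = peaks / frame_rate,
                value = v[peaks])
  attr(out, "frame_rate") <- frame_rate
  attr(out, "kind") <- kind
  class(out) <- c("pulse_train", class(out))
  out
}

#' Summarise inter-pulse intervals
#'
#' Mean and standard deviation of the intervals between successive pulses,
#' and the pulse frequency defined as the reciprocal of the mean interval
#' (not the mean of reciprocals). With fewer than two pulses the summary is
#' undefined and the statistics are `NA`.
#'
#' @param train A `pulse_train` from [detect_pulses()], or a numeric vector
#'   of pulse times in seconds.
#' @return A one-row tibble: `n_pulses`, `mean_interval`, `sd_interval`,
#'   `pulse_frequency` (Hz).
#' @export
interpulse_summary <- function(train) {
  times <- if (is.numeric(train)) sort(train) else train$time
  n <- length(times)
  if (n < 2) {
    return(tibble(n_pulses = n, mean_interval = NA_real_,
                  sd_interval = NA_real_, pulse_frequency = NA_real_))
  }
  iv <- diff(times)
  tibble(n_pulses = n,
         mean_interval = mean(iv),
         sd_interval = if (n > 2) sd(iv) else 0,
         pulse_frequency = 1 / mean(iv))
}

# ARPAbet vowel inventory (stress digits stripped before matching),
# including syllabic ER so "bird" is V + one coda.
arpabet_vowels <- c("AA", "AE", "AH", "AO", "AW", "AX", "AXR", "AY",
                    "EH", "ER", "EY", "IH", "IX", "IY", "OW", "OY",
                    "UH", "UW", "UX")

#' Classify a syllable's coda from its phone labels
#'
#' Counts consonant phones after the last vowel phone of the syllable:
#' 0 gives `"open"`, 1 `"one_coda"`, 2 or more `"multi_coda"`. Phones are
#' ARPAbet labels; trailing stress digits are ignored. A syllable with no
#' vowel is unclassifiable and returns `NA`.
#'
#' @param phones Character vector of ARPAbet phone labels, in order.
#' @return One of `"open"`, `"one_coda"`, `"multi_coda"`, or `NA_character_`.
#' @export
classify_coda <- function(phones) {
  p <- toupper(gsub("[0-9]+$", "", trimws(phones)))
  p <- p[p != ""]
  is_vowel <- p %in% arpabet_vowels
  if (!any(is_vowel)) return(NA_character_)
  n_coda <- length(p) - max(which(is_vowel))
  if (n_coda == 0) "open" else if (n_coda == 1) "one_coda" else "multi_coda"
}

#' Tally modulation pulses per syllable
#'
#' Counts, for each syllable interval, the pulses whose times fall in the
#' half-open window `[start, end)`, then averages the counts within each
#' coda class. Pulses landing inside a pause are excluded silently (the
#' syllable windows exclude the pause); pulses outside all syllables and all
#' pauses are excluded with a warning.
#'
#' @param train A `pulse_train` (or numeric pulse times, seconds).
#' @param seg A [syllable_segmentation()].
#' @return A list of class `syllable_tally`: `per_syllable` (tibble with one
#'   row per syllable: `label`, `start`, `end`, `coda_class`, `n_pulses`) and
#'   `class_means` (tibble `coda_class`, `n_syllables`, `mean_pulses`).
#' @export
tally_pulses_by_syllable <- function(train, seg) {
  times <- if (is.numeric(train)) train else train$time
  iv <- as_tibble(seg)
  counts <- vapply(seq_len(nrow(iv)), function(i) {
    sum(times >= iv$start[i] & times < iv$end[i])
  }, integer(1))
  pauses <- attr(seg, "pauses")
  in_syll <- vapply(times, function(t) any(t >= iv$start & t < iv$end), logical(1))
  in_pause <- if (nrow(pauses) > 0) {
    vapply(times, function(t) any(t >= pauses$start & t < pauses$end), logical(1))
  } else rep(FALSE, length(times))
  stray <- sum(!in_syll & !in_pause)
  if (stray > 0) {
    warn(sprintf("%d pulse(s) outside all syllables and pauses were excluded.", stray))
  }
  per <- tibble(label = iv$label, start = iv$start, end = iv$end,
                coda_class = iv$coda_class, n_pulses = counts)
  cls <- per |>
    filter(!is.na(.data$coda_class)) |>
    mutate(coda_class = factor(.data$coda_class,
                               levels = c("open", "one_coda", "multi_coda"))) |>
    group_by(.data$coda_class, .drop = FALSE) |>
    summarise(n_syllables = n(),
              mean_pulses = dplyr::coalesce(mean(.data$n_pulses), 0),
              .groups = "drop")
  structure(list(per_syllable = per, class_means = cls),
            class = "syllable_tally")
}

#' @export
print.syllable_tally <- function(x, ...) {
  cat("<syllable_tally>\n")
  print(x$class_means)
  invisible(x)
}

#' Count syllables in a word sequence
#'
#' Each word counts one syllable except words in the disyllabic lexicon,
#' which count two. Case and punctuation are ignored.
#'
#' @param words Character vector of words.
#' @param disyllabic Character vector of known two-syllable words.
#' @return Integer syllable count.
#' @export
count_syllables <- function(words, disyllabic = c("during", "winter")) {
  w <- tolower(gsub("[^a-zA-Z']", "", words))
  w <- w[w != ""]
  sum(1L + as.integer(w %in% tolower(disyllabic)))
}

#' Estimate the syllable rate of an utterance
#'
#' Speech time is the utterance duration minus all pause durations; the mean
#' syllable duration is speech time divided by the syllable count, and the
#' rate is its reciprocal.
#'
#' @param duration Utterance duration, seconds.
#' @param pause_durations Numeric vector of pause durations, seconds.
#' @param n_syllables Number of syllables (> 0).
#' @return One-row tibble: `speech_time`, `n_syllables`,
#'   `mean_syllable_duration` (s), `syllable_rate` (Hz).
#' @export
estimate_syllable_rate <- function(duration, pause_durations = numeric(0),
                                   n_syllables) {
  if (n_syllables <= 0) abort("n_syllables must be positive.", class = "comod_domain_error")
  speech <- duration - sum(pause_durations)
  if (speech <= 0) {
    abort("Pause time meets or exceeds utterance duration.", class = "comod_domain_error")
  }
  msd <- speech / n_syllables
  tibble(speech_time = speech, n_syllables = as.integer(n_syllables),
         mean_syllable_duration = msd, syllable_rate = 1 / msd)
}
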