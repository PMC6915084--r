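#' Analyse one speaker's paired articulatory/acoustic recording
#'
#' Runs the full single-speaker analysis: articulatory and acoustic
#' modulation functions at the configured cutoff, pulse detection and
#' inter-pulse summaries, pulse tallies per syllable coda class, syllable
#' rate, overall correlation, windowed-correlation lag sweeps for every
#' `eta` (original and half-swap surrogate pairing), per-eta extreme
#' selection, and — for the sharpest window — lag extrema and the positive
#' threshold lag.
#'
#' @param trajectory A [marker_trajectory()].
#' @param acoustics A [feature_matrix()] (or an [audio_signal()], converted
#'   through [compute_mfcc_features()] with `config$mfcc`).
#' @param segmentation A [syllable_segmentation()].
#' @param config A [run_config()].
#' @param speaker Speaker id used in output tables.
#' @return A list of class `speaker_analysis` with elements
#'   `pulse_summary`, `tally`, `syllable_rate`, `overall`, `extremes`
#'   (per condition x eta), `lag_profile` (sharpest eta, original pair),
#'   `extrema`, `threshold`.
#' @export
analyze_speaker <- function(trajectory, acoustics, segmentation,
                            config = run_config(), speaker = "S01") {
  if (inherits(acoustics, "audio_signal")) {
    mc <- config$mfcc %||% mfcc_config(frame_rate = frame_rate(trajectory),
                                       cutoff = config$smoothing_cutoff)
    acoustics <- compute_mfcc_features(acoustics, mc)
  }
  fr <- frame_rate(trajectory)
  mbeam <- compute_mbeam(trajectory, cutoff = config$smoothing_cutoff)
  mfccm <- compute_mfcc_modulation(acoustics, cutoff = config$smoothing_cutoff)
  n <- min(nrow(mbeam), nrow(mfccm))
  xb <- mbeam$value[seq_len(n)]
  xa <- mfccm$value[seq_len(n)]

  pb <- detect_pulses(mbeam)
  pa <- detect_pulses(mfccm)
  pulse_summary <- bind_rows(
    mutate(interpulse_summary(pb), signal = "articulatory", .before = 1),
    mutate(interpulse_summary(pa), signal = "acoustic", .before = 1))
  tally <- tally_pulses_by_syllable(pb, segmentation)
  span <- attr(segmentation, "utterance_span")
  pauses <- attr(segmentation, "pauses")
  syll_rate <- estimate_syllable_rate(diff(span),
                                      pauses$end - pauses$start,
                                      nrow(segmentation))
  overall <- overall_correlation(xb, xa, seed = config$random_seed)

  xs <- make_surrogate(xa)
  extremes <- purrr::map(config$eta_values, function(e) {
    k <- kernel_weights(e)
    po <- lag_sweep(xb, xa, k, config$lag_range_ms, fr)
    ps <- lag_sweep(xb, xs, k, config$lag_range_ms, fr)
    bind_rows(
      mutate(select_speaker_extreme(po), condition = "original"),
      mutate(select_speaker_extreme(ps), condition = "surrogate")) |>
      mutate(eta = e, median_rho_lag0 = c(
        po$median_rho[po$lag_frames == 0], ps$median_rho[ps$lag_frames == 0]))
  }) |> bind_rows() |> mutate(speaker = speaker, .before = 1)

  eta_max <- max(config$eta_values)
  prof <- lag_sweep(xb, xa, kernel_weights(eta_max), config$lag_range_ms, fr)
  extrema <- find_lag_extrema(prof, config$search_limit_ms)
  threshold <- positive_threshold_lag(prof)

  structure(list(speaker = speaker,
                 pulse_summary = mutate(pulse_summary, speaker = speaker, .before = 1),
                 tally = tally,
                 syllable_rate = mutate(syll_rate, speaker = speaker, .before = 1),
                 overall = mutate(overall, speaker = speaker, .before = 1),
                 extremes = extremes,
                 lag_profile = prof,
                 extrema = extrema,
                 threshold = mutate(threshold, speaker = speaker, .before = 1)),
            class = "speaker_analysis")
}

#' Run the end-to-end co-modulation pipeline over a corpus
#'
#' Applies [analyze_speaker()] to every speaker, then assembles the
#' cross-speaker tables: pulse summaries and syllable-class tallies,
#' syllable rates, overall correlations, per-eta original-vs-surrogate
#' comparison (sign tests and lag dispersion), and secondary-maximum lag
#' statistics. With `out_dir` set, tables are written as CSV plus a single
#' JSON report; outputs are deterministic given `config$random_seed`.
#'
#' @param speakers A list of speakers as produced by [generate_corpus()]
#'   (each with `trajectory`, `features` or `audio`, `segmentation`; an
#'   optional `speaker` id).
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `pipeline_report`: `pulse_summaries`, `tallies`,
#'   `syllable_rates`, `overall`, `extremes`, `comparison`
#'   ([compare_original_vs_surrogate()] output), `secondary_lags`,
#'   `thresholds`, `per_speaker` (the `speaker_analysis` objects).
#' @export
run_pipeline <- function(speakers, config = run_config(), out_dir = NULL) {
  if (length(speakers) == 0) {
    abort("Empty speaker list.", class = "comod_config_error")
  }
  rates <- vapply(speakers, function(s) frame_rate(s$trajectory), numeric(1))
  if (max(rates) - min(rates) > 1e-9) {
    abort("All speakers must share a frame rate.", class = "comod_config_error")
  }
  analyses <- purrr::imap(speakers, function(s, i) {
    analyze_speaker(s$trajectory,
                    s$features %||% s$audio,
                    s$segmentation,
                    config,
                    speaker = s$speaker %||% sprintf("S%02d", i))
  })
  tallies <- purrr::map(analyses, function(a) {
    mutate(a$tally$class_means, speaker = a$speaker, .before = 1)
  }) |> bind_rows()
  extremes <- bind_rows(purrr::map(analyses, "extremes"))
  comparison <- compare_original_vs_surrogate(extremes)
  secondary <- purrr::map(analyses, function(a) {
    tibble(speaker = a$speaker,
           primary_max_lag_ms = a$extrema$primary_max_lag_ms,
           secondary_lag_avg_ms = a$extrema$secondary_lag_avg_ms,
           has_secondary = a$extrema$has_secondary)
  }) |> bind_rows()
  report <- structure(
    list(pulse_summaries = bind_rows(purrr::map(analyses, "pulse_summary")),
         tallies = tallies,
         syllable_rates = bind_rows(purrr::map(analyses, "syllable_rate")),
         overall = bind_rows(purrr::map(analyses, "overall")),
         extremes = extremes,
         comparison = comparison,
         secondary_lags = secondary,
         thresholds = bind_rows(purrr::map(analyses, "threshold")),
         per_speaker = analyses),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d speaker(s)>\n", length(x$per_speaker)))
  cat("Pulse-per-syllable class means (cross-speaker):\n")
  print(x$tallies |> group_by(.data$coda_class) |>
          summarise(mean_pulses = mean(.data$mean_pulses), .groups = "drop"))
  cat("Original vs surrogate sign tests:\n")
  print(x$comparison$sign_tests)
  invisible(x)
}

# Serialize the cross-speaker tables (CSV) and a JSON report.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("pulse_summaries", "tallies", "syllable_rates", "overall",
            "extremes", "secondary_lags", "thresholds")
  for (nm in tabs) {
    readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  readr::write_csv(report$comparison$sign_tests,
                   file.path(out_dir, "surrogate_sign_tests.csv"))
  readr::write_csv(report$comparison$lag_summary,
                   file.path(out_dir, "lag_summary.csv"))
  json <- list(n_speakers = length(report$per_speaker),
               tallies = report$tallies,
               syllable_rates = report$syllable_rates,
               overall = report$overall,
               sign_tests = report$comparison$sign_tests,
               lag_summary = report$comparison$lag_summary,
               secondary_lags = report$secondary_lags,
               thresholds = report$thresholds)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, dataframe = "rows",
                       na = "null")
  invisible(out_dir)
}
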