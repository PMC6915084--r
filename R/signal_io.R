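#' Construct a marker trajectory
#'
#' A marker trajectory holds midsagittal fleshpoint positions for the seven
#' standard markers (UL, LL, T1--T4, LI), each in two spatial dimensions
#' (x, y), sampled at a fixed frame rate. The 14 channels are stored in the
#' canonical order `UL.x, UL.y, LL.x, ..., LI.y`; frame `i` is at time
#' `(i - 1) / frame_rate` seconds.
#'
#' @param positions A data frame or matrix with the 14 canonical channel
#'   columns (any column order if named; positional if unnamed).
#' @param frame_rate Sampling rate in Hz (the microbeam-style corpora use
#'   145.6 Hz).
#' @return A tibble of class `marker_trajectory` with a `time` column and the
#'   14 channel columns, carrying `frame_rate` as an attribute.
#' @export
marker_trajectory <- function(positions, frame_rate) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number.", class = "comod_config_error")
  }
  ch <- mb_channels()
  pos <- as.data.frame(positions)
  if (!is.null(colnames(positions)) && any(colnames(positions) != "")) {
    missing <- setdiff(ch, colnames(pos))
    if (length(missing) > 0) {
      abort(paste0("Missing marker channel column(s): ", paste(missing, collapse = ", ")),
            class = "comod_format_error")
    }
    pos <- pos[ch]
  } else {
    if (ncol(pos) != 14) {
      abort(sprintf("Expected 14 marker channels, got %d.", ncol(pos)),
            class = "comod_format_error")
    }
    colnames(pos) <- ch
  }
  for (j in seq_along(pos)) {
    if (!is.numeric(pos[[j]]) || anyNA(pos[[j]]) || any(!is.finite(pos[[j]]))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(pos[[j]]))))[1]
      abort(sprintf("Non-numeric or missing value in channel '%s' at row %d.",
                    colnames(pos)[j], if (is.na(bad)) 1L else bad),
            class = "comod_parse_error")
    }
  }
  out <- as_tibble(pos)
  out <- tibble(time = (seq_len(nrow(out)) - 1) / frame_rate, !!!out)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("marker_trajectory", class(out))
  out
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory: %d frames x 14 channels @ %.6g Hz>\n",
              nrow(x), attr(x, "frame_rate")))
  NextMethod()
}

# Extract the frames x 14 numeric matrix from a marker_trajectory.
trajectory_matrix <- function(traj) {
  as.matrix(traj[mb_channels()])
}

#' Frame rate of a signal object
#'
#' @param x A `marker_trajectory`, `feature_matrix`, or `modulation_function`.
#' @return Frame rate in Hz.
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' Read marker trajectories from a delimited file
#'
#' Reads a whitespace/tab-delimited table of marker positions. The file may
#' have a header row naming the 14 canonical channels (in any order; columns
#' are reordered by name), or exactly 14 unnamed numeric columns taken in
#' canonical order. The frame rate is taken from the `frame_rate` argument,
#' or, if `NULL`, from a JSON sidecar `<path>.json` with a `frame_rate` field.
#'
#' @param path Path to the TSV file.
#' @param frame_rate Frame rate in Hz, or `NULL` to read the sidecar.
#' @return A [marker_trajectory()].
#' @export
read_marker_trajectories <- function(path, frame_rate = NULL) {
  if (is.null(frame_rate)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      abort("No `frame_rate` given and no JSON sidecar found.",
            class = "comod_config_error")
    }
    frame_rate <- jsonlite::read_json(sidecar)$frame_rate
  }
  first <- readLines(path, n = 1)
  fields <- strsplit(trimws(first), "[ \t,]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  tab <- utils::read.table(path, header = has_header, colClasses = "character",
                           check.names = FALSE)
  if (has_header) {
    missing <- setdiff(mb_channels(), colnames(tab))
    if (length(missing) > 0) {
      abort(paste0("Marker file is missing column(s): ",
                   paste(missing, collapse = ", ")),
            class = "comod_format_error")
    }
    tab <- tab[mb_channels()]
  } else if (ncol(tab) != 14) {
    abort(sprintf("Marker file must have 14 columns, found %d.", ncol(tab)),
          class = "comod_format_error")
  }
  num <- lapply(tab, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column %d at data row %d.", j, bad[1]),
            class = "comod_parse_error")
    }
  }
  marker_trajectory(as.data.frame(num, col.names = colnames(tab)), frame_rate)
}

#' Write marker trajectories to a TSV file
#'
#' Writes the canonical 14-column TSV (header row of channel names) plus a
#' JSON sidecar `<path>.json` holding the frame rate, so that
#' [read_marker_trajectories()] can recover the trajectory exactly.
#'
#' @param traj A [marker_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_trajectories <- function(traj, path) {
  mat <- as.data.frame(trajectory_matrix(traj))
  readr::write_tsv(mat, path)
  jsonlite::write_json(list(frame_rate = frame_rate(traj)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a syllable segmentation
#'
#' Time intervals (seconds) labelling the syllables of an utterance, each
#' annotated with a coda class: `open` (no coda consonant), `one_coda`
#' (a single coda consonant), or `multi_coda` (two or more). Intervals are
#' half-open `[start, end)` for all containment tests.
#'
#' @param intervals A data frame with columns `start`, `end`, `label`, and
#'   optionally `coda_class`. When `coda_class` is absent, labels are treated
#'   as space-separated ARPAbet phone strings and classified with
#'   [classify_coda()].
#' @param utterance_span Length-2 numeric `(start, end)` of the utterance;
#'   defaults to the span of the intervals.
#' @param pauses Optional data frame of pause intervals (`start`, `end`).
#' @return A tibble of class `syllable_segmentation`.
#' @export
syllable_segmentation <- function(intervals, utterance_span = NULL, pauses = NULL) {
  iv <- as_tibble(intervals)
  if (nrow(iv) == 0) {
    abort("Segmentation has no intervals.", class = "comod_validation_error")
  }
  if (!all(c("start", "end", "label") %in% names(iv))) {
    abort("Intervals need `start`, `end`, `label` columns.",
          class = "comod_format_error")
  }
  iv$start <- as.numeric(iv$start)
  iv$end <- as.numeric(iv$end)
  iv <- arrange(iv, .data$start)
  if (any(iv$end <= iv$start)) {
    abort("Each interval must satisfy start < end.", class = "comod_validation_error")
  }
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-12)) {
    abort("Intervals overlap.", class = "comod_validation_error")
  }
  if (!"coda_class" %in% names(iv) || all(is.na(iv$coda_class))) {
    iv$coda_class <- vapply(strsplit(as.character(iv$label), "[ _-]+"),
                            classify_coda, character(1))
  }
  ok <- iv$coda_class %in% c("open", "one_coda", "multi_coda") | is.na(iv$coda_class)
  if (!all(ok)) {
    abort("coda_class must be one of open/one_coda/multi_coda (or NA).",
          class = "comod_validation_error")
  }
  if (is.null(utterance_span)) {
    utterance_span <- c(min(iv$start), max(iv$end))
  }
  pauses <- if (is.null(pauses)) {
    tibble(start = numeric(0), end = numeric(0))
  } else {
    as_tibble(pauses)[c("start", "end")]
  }
  attr(iv, "utterance_span") <- as.numeric(utterance_span)
  attr(iv, "pauses") <- pauses
  class(iv) <- c("syllable_segmentation", class(iv))
  iv
}

#' Read a syllable segmentation from TSV or Praat TextGrid
#'
#' TSV files must have columns `start end label` and optionally `coda_class`.
#' TextGrid files (long text format) are read from their first
#' interval tier named `words`/`word` (or the first interval tier otherwise);
#' empty and silence labels (`""`, `sp`, `sil`, `<p:>`) become pauses. When a
#' `phones` tier is present, coda classes are derived from the phones inside
#' each word interval; otherwise word labels are classified directly via
#' [classify_coda()] (useful when labels are phone strings).
#'
#' @param path Path to a `.TextGrid` or delimited text file.
#' @return A [syllable_segmentation()].
#' @export
read_segmentation <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("ooTextFile", txt[seq_len(min(3, length(txt)))]))) {
    return(read_textgrid_segmentation(txt))
  }
  # tab-separated if tabs are present (labels may contain spaces),
  # whitespace-separated otherwise
  sep <- if (grepl("\t", txt[1])) "\t" else ""
  tab <- utils::read.table(path, header = FALSE, sep = sep, quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || ncol(tab) > 4) {
    abort("Segmentation TSV needs start, end, label (+ optional coda_class) columns.",
          class = "comod_format_error")
  }
  names(tab) <- c("start", "end", "label", "coda_class")[seq_len(ncol(tab))]
  syllable_segmentation(tab)
}

# Minimal Praat TextGrid (long text format) interval-tier parser.
parse_textgrid_tiers <- function(txt) {
  nums <- function(x) as.numeric(sub(".*= *", "", x))
  strs <- function(x) gsub("^\"|\"$", "", sub(".*= *", "", trimws(x)))
  tiers <- list()
  # Long format: an `item []:` header line, then one `item [k]:` block per tier
  items <- grep("item *\\[", txt)
  if (length(items) > 1) {
    for (k in seq_along(items)[-1]) {
      block <- txt[items[k]:(c(items[-(1:k)], length(txt) + 1)[1] - 1)]
      if (!any(grepl("IntervalTier", block))) next
      name <- strs(grep("name *=", block, value = TRUE)[1])
      xmin <- nums(grep("xmin *=", block, value = TRUE))
      xmax <- nums(grep("xmax *=", block, value = TRUE))
      labs <- strs(grep("text *=", block, value = TRUE))
      # first xmin/xmax pair is the tier span; the rest are intervals
      if (length(xmin) > 1) {
        tiers[[name]] <- tibble(start = xmin[-1], end = xmax[-1], label = labs)
      }
    }
  }
  tiers
}

read_textgrid_segmentation <- function(txt) {
  tiers <- parse_textgrid_tiers(txt)
  if (length(tiers) == 0) {
    abort("No interval tier found in TextGrid.", class = "comod_validation_error")
  }
  word_tier <- tiers[[intersect(c("words", "word"), names(tiers))[1] %||% 1]]
  silence <- c("", "sp", "sil", "<p:>", "pause")
  words <- filter(word_tier, !(tolower(.data$label) %in% silence))
  pauses <- filter(word_tier, tolower(.data$label) %in% silence)
  if (nrow(words) == 0) {
    abort("Word tier is empty.", class = "comod_validation_error")
  }
  phone_name <- intersect(c("phones", "phone"), names(tiers))
  if (length(phone_name) > 0) {
    phones <- tiers[[phone_name[1]]]
    words$coda_class <- vapply(seq_len(nrow(words)), function(i) {
      inside <- phones$label[phones$start >= words$start[i] - 1e-9 &
                               phones$end <= words$end[i] + 1e-9 &
                               phones$label != ""]
      classify_coda(inside)
    }, character(1))
  }
  syllable_segmentation(words,
                        utterance_span = c(min(word_tier$start), max(word_tier$end)),
                        pauses = pauses[c("start", "end")])
}

#' Write a syllable segmentation as TSV
#'
#' @param seg A [syllable_segmentation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  readr::write_tsv(as_tibble(seg)[c("start", "end", "label", "coda_class")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Construct an audio signal
#'
#' @param samples Numeric vector of mono samples.
#' @param sample_rate Sampling rate in Hz.
#' @return A list of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (sample_rate <= 0) abort("sample_rate must be positive.", class = "comod_config_error")
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("Audio samples must be finite.", class = "comod_validation_error")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 16-bit mono PCM, returning
#' samples scaled to `[-1, 1]`.
#'
#' @param path Path to the WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") abort("Not a RIFF/WAVE file.", class = "comod_format_error")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") {
    abort("Not a RIFF/WAVE file.", class = "comod_format_error")
  }
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(bits)) abort("WAV data chunk before fmt chunk.", class = "comod_format_error")
      n <- size %/% (bits %/% 8)
      samples <- readBin(con, "integer", n, size = bits %/% 8, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(samples)) abort("No data chunk found.", class = "comod_format_error")
  if (channels != 1) abort("Only mono WAV supported.", class = "comod_format_error")
  audio_signal(samples / (2^(bits - 1)), sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param audio An [audio_signal()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Run configuration for the co-modulation pipeline
#'
#' @param smoothing_cutoff Low-pass cutoff (Hz) for the modulation functions;
#'   12 Hz is the primary condition, 25 Hz the replication condition.
#' @param eta_values Kernel sharpness values for the windowed correlation.
#' @param lag_range_ms Half-width of the lag sweep in ms.
#' @param search_limit_ms Outer limit for the secondary-maximum search, ms.
#' @param mfcc Optional [mfcc_config()] used when speakers carry raw audio.
#' @param random_seed Seed for the (few) stochastic steps, e.g. permutation
#'   p-values for per-speaker overall correlations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(smoothing_cutoff = 12, eta_values = c(0.08, 0.2, 0.8),
                       lag_range_ms = 200, search_limit_ms = 170,
                       mfcc = NULL, random_seed = 1L) {
  if (smoothing_cutoff <= 0) abort("smoothing_cutoff must be > 0.", class = "comod_config_error")
  if (lag_range_ms <= 0) abort("lag_range_ms must be > 0.", class = "comod_config_error")
  if (any(eta_values <= 0)) abort("eta values must be > 0.", class = "comod_config_error")
  structure(list(smoothing_cutoff = smoothing_cutoff,
                 eta_values = sort(eta_values),
                 lag_range_ms = lag_range_ms,
                 search_limit_ms = search_limit_ms,
                 mfcc = mfcc,
                 random_seed = as.integer(random_seed)),
            class = "run_config")
}
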