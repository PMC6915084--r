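test_that("marker trajectory TSV round-trips at full precision and honours headers", {
  set.seed(10)
  pos <- matrix(rnorm(5 * 14), 5, 14)
  colnames(pos) <- c("UL.x", "UL.y", "LL.x", "LL.y", "T1.x", "T1.y", "T2.x",
                     "T2.y", "T3.x", "T3.y", "T4.x", "T4.y", "LI.x", "LI.y")
  traj <- marker_trajectory(pos, 145.6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_trajectories(traj, path)
  back <- read_marker_trajectories(path)
  expect_equal(as.matrix(back[colnames(pos)]), pos, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(frame_rate(back), 145.6)

  # permuted columns reorder by name to the identical trajectory
  perm <- sample(ncol(pos))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(as.data.frame(pos[, perm]), path2)
  back2 <- read_marker_trajectories(path2, frame_rate = 145.6)
  expect_equal(as.matrix(back2[colnames(pos)]), pos, ignore_attr = TRUE)

  # zero case
  z <- marker_trajectory(matrix(0, 3, 14), 145.6)
  expect_equal(nrow(z), 3)
  expect_true(all(as.matrix(z[setdiff(names(z), "time")]) == 0))
})

test_that("marker reader rejects malformed tables with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(as.data.frame(matrix(0, 3, 13)), path)
  expect_error(read_marker_trajectories(path, 145.6), class = "comod_format_error")

  # missing named column
  pos <- as.data.frame(matrix(0, 2, 14))
  names(pos) <- c("UL.x", "UL.y", "LL.x", "LL.y", "T1.x", "T1.y", "T2.x",
                  "T2.y", "T3.x", "T3.y", "T4.x", "T4.y", "LI.x", "BAD")
  readr::write_tsv(pos, path)
  expect_error(read_marker_trajectories(path, 145.6), "LI.y",
               class = "comod_format_error")

  # non-numeric cell reported with its row
  lines <- c(paste(rep(0, 14), collapse = "\t"),
             paste(c("x", rep(0, 13)), collapse = "\t"))
  writeLines(lines, path)
  expect_error(read_marker_trajectories(path, 145.6), "row 2",
               class = "comod_parse_error")

  expect_error(marker_trajectory(matrix(0, 2, 14), -1),
               class = "comod_config_error")
})

test_that("segmentation reader parses TSV, validates ordering, derives coda class", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0.0\t0.2\tonce\tone_coda", path)
  seg <- read_segmentation(path)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$coda_class, "one_coda")

  writeLines(c("0.0\t0.2\ta\topen", "0.15\t0.3\tb\topen"), path)
  expect_error(read_segmentation(path), class = "comod_validation_error")

  # no coda_class column: derived from phone-string labels
  writeLines(c("0.0\t0.2\tHH IY", "0.2\t0.5\tW AH N S"), path)
  seg2 <- read_segmentation(path)
  expect_equal(seg2$coda_class, c("open", "multi_coda"))

  expect_error(syllable_segmentation(tibble::tibble(start = 0.2, end = 0.1,
                                                    label = "x")),
               class = "comod_validation_error")
})

test_that("TextGrid word+phone tiers give intervals with derived coda classes", {
  tg <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 2", "item []:",
    "    item [1]:", '        class = "IntervalTier"', '        name = "words"',
    "        xmin = 0", "        xmax = 1", "        intervals: size = 3",
    "        intervals [1]:", "            xmin = 0", "            xmax = 0.3",
    '            text = "he"',
    "        intervals [2]:", "            xmin = 0.3", "            xmax = 0.5",
    '            text = "sp"',
    "        intervals [3]:", "            xmin = 0.5", "            xmax = 1",
    '            text = "once"',
    "    item [2]:", '        class = "IntervalTier"', '        name = "phones"',
    "        xmin = 0", "        xmax = 1", "        intervals: size = 6",
    "        intervals [1]:", "            xmin = 0", "            xmax = 0.15",
    '            text = "HH"',
    "        intervals [2]:", "            xmin = 0.15", "            xmax = 0.3",
    '            text = "IY1"',
    "        intervals [3]:", "            xmin = 0.3", "            xmax = 0.5",
    '            text = ""',
    "        intervals [4]:", "            xmin = 0.5", "            xmax = 0.7",
    '            text = "W"',
    "        intervals [5]:", "            xmin = 0.7", "            xmax = 0.85",
    '            text = "AH1"',
    "        intervals [6]:", "            xmin = 0.85", "            xmax = 1",
    '            text = "N"')
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(tg, path)
  seg <- read_segmentation(path)
  expect_equal(seg$label, c("he", "once"))
  expect_equal(seg$coda_class, c("open", "one_coda"))
  expect_equal(nrow(attr(seg, "pauses")), 1)
  expect_equal(attr(seg, "pauses")$start, 0.3)
})

test_that("mono PCM WAV files round-trip within quantization error", {
  x <- 0.5 * sin(2 * pi * 440 * (0:8000) / 16000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(x, 16000), path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 16000)
  expect_lt(max(abs(back$samples - x)), 1 / 32767 + 1e-12)
})

test_that("run configuration validates its parameters", {
  expect_error(run_config(smoothing_cutoff = 0), class = "comod_config_error")
  expect_error(run_config(lag_range_ms = -5), class = "comod_config_error")
  expect_error(run_config(eta_values = c(0.2, -1)), class = "comod_config_error")
  cfg <- run_config()
  expect_equal(cfg$eta_values, c(0.08, 0.2, 0.8))
})
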