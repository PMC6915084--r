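Package: comodulate
Title: Temporal Co-Modulation Analysis of Articulatory and Acoustic Speech Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much speech articulation and acoustics
    are changing over time, and how tightly the two change patterns are
    coupled. Computes articulatory (marker kinetic-energy) and acoustic
    (mel-cepstral) modulation functions from paired point-tracking and audio
    data, detects syllable-scale modulation pulses and relates them to
    syllable structure, and measures time-resolved co-modulation with
    kernel-windowed (exponentially weighted) correlation, including lag
    sweeps, secondary-maximum periodicity estimation, and half-swap surrogate
    null comparisons. A seeded synthetic-data generator with known ground
    truth supports end-to-end validation without access to restricted
    articulatory corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
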