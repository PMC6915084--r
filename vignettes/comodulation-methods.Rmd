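---
title: "Methods: temporal co-modulation of articulation and acoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal co-modulation of articulation and acoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comodulate)
```

## The model

`comodulate` quantifies the *temporal modulation* of speech — how much a
signal is changing at each moment — separately for articulation and
acoustics, and then measures how tightly the two modulation patterns are
coupled in time.

Both modulation functions share one core: the sum over channels of squared
frame-to-frame differences (`frame_difference_energy()`). For the
articulatory side the channels are 7 midsagittal markers × 2 dimensions;
with unit masses, the result is twice the kinetic energy of the articulator
set. For the acoustic side the channels are 13 mel-cepstral coefficients
computed with the hop locked to the kinematic frame rate. Differencing is
inherently high-pass, so both series are smoothed with a zero-phase
low-pass filter before any further analysis.

Coupling is measured with a kernel-windowed correlation: at each sample,
covariance and variances are accumulated under a symmetric exponentially
decaying kernel `w(l) ∝ exp(−η·|l|)`, normalized to sum to 1, and their
ratio gives a per-sample correlation. Sweeping an integer-frame lag
between the two series and taking the median correlation per lag yields a
lag profile that behaves like an autocorrelation function: a primary
maximum where the signals align causally (near zero lag), minima on either
side, and secondary maxima at the period of repetition shared by the two
pulse trains.

The null model is the *half-swap surrogate*: the two halves of one series
are exchanged, destroying temporal alignment while preserving the value
distribution and the within-half signal structure. Original-vs-surrogate
contrasts use exact two-sided sign tests on per-speaker differences of
correlation magnitudes (magnitudes, because surrogate correlations vary in
sign).

### Assumptions

- Articulatory change causes acoustic change with negligible delay
  relative to a 6.9 ms frame, so the causal alignment appears at (or
  within one frame of) zero lag.
- Marker kinematics are band-limited well below the smoothing cutoff; the
  spectrum diagnostic (`magnitude_spectrum()`) lets users confirm this on
  their own data (kinematic energy typically falls by ~60 dB by 10 Hz).
- Syllable-level segmentations are given (from a forced aligner or by
  hand); the package validates but never edits them.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| smoothing cutoff | Hz | 12 (25 as check) | just above the kinematic band edge; 25 Hz replication shows results are not filter artifacts |
| filter | — | order-4 Butterworth, forward–backward | zero phase preserves pulse times; 9 coefficients per pass |
| η (kernel sharpness) | per frame | 0.08 / 0.2 / 0.8 | effective cutoffs ≈1.2 / 3 / 12.4 Hz at 145.6 Hz; narrow-to-wide windows probe the time scale of the coupling |
| kernel truncation | — | 1e-8 | bounds the truncated tail mass; weights renormalized to sum to exactly 1 |
| lag range | ms | ±200 | covers a syllable-scale period on both sides |
| secondary-max search limit | ms | ±170 | beyond the first minima, below the alias of two periods |
| MFCC | — | 25 ms window, hop = 1 frame, preemphasis 0.97, 20 mel filters 0–3700 Hz, c1–c13 | anterior-articulator-determined band; c0 excluded so features track resonance structure, not level (`include_c0` switches dialect) |
| frame rate | Hz | 145.6 | microbeam-style corpus convention (6.866 ms frames) |

## Numerical choices

- **Zero-phase filtering** pads by odd reflection and starts each pass in
  steady state for the first sample's level, so constant series pass
  through bit-near-exactly and boundary transients do not masquerade as
  pulses near utterance edges.
- **Post-smoothing negatives** in modulation functions are clipped to 0:
  modulation is a change magnitude, and clipping preserves maxima
  locations.
- **Pulse detection** takes sign changes (+ to −) of the first difference;
  a plateau contributes its first frame; endpoints are never pulses.
  Pulse frequency is the reciprocal of the mean inter-pulse interval, not
  the mean of reciprocals.
- **Windowed correlation** is computed by FFT convolution of elementwise
  products with the truncated kernel; near boundaries the kernel mass
  falling outside the series is renormalized over the available samples
  rather than zero-padded (zero-padding would attenuate edges). Samples
  with numerically zero local variance are reported as missing and
  excluded from medians. Correlations are clamped to [−1, 1].
- **Centering**: the covariance removes kernel-weighted local means by
  default (weighted Pearson). The raw product form is available
  (`center = FALSE`), but uncentred correlations of nonnegative modulation
  signals can never be negative, which contradicts the need to represent
  anticorrelation; centering is therefore the default.
- **Secondary maxima** are found as the argmax of the lag profile between
  the near-zero minimum and the search limit on each side (the most
  extreme of multiple nearby maxima). Each is referenced to the
  primary-maximum lag, and the positive and |negative| referenced lags are
  averaged. Profiles without minima on a side (e.g. monotone decay) are
  flagged rather than forced.
- **Ties** in the per-speaker extreme selection break toward the positive
  extreme; zero differences are dropped from sign tests (standard exact
  sign test).
- **η-to-cutoff** is computed numerically as the −3 dB point of the
  truncated kernel's discrete frequency response; in the small-η limit it
  approaches `η·√(√2−1)` rad/frame.
- **Half-open intervals** `[start, end)` govern all pulse-to-syllable
  assignment, making boundary pulses unambiguous; a pulse exactly at a
  boundary belongs to the following syllable.
- Odd-length surrogates split at `floor(n/2)`.

## What the synthetic generator emulates

`generate_corpus()` produces the structure the pipeline expects from a
microbeam-style recording session:

- **Kinematics**: each syllable contributes one onset-release gesture plus
  one gesture per coda consonant; each gesture drives a random subset of
  the 14 channels through a critically damped second-order transition
  (time constant 40 ms — velocity peaks 40 ms after gesture onset, and the
  resulting kinematics stay below ~10 Hz). Coda gestures occupy roughly
  fixed slots at the syllable end, as coda consonants do. Gesture velocity
  peaks are recorded as planted ground-truth pulse times.
- **Acoustics**: 13 feature channels are a fixed random smooth nonlinear
  (tanh-of-linear) mixture of the standardized articulatory channels,
  mixed with *independently timed* gesture-structured channels standing in
  for articulatory dimensions the markers miss (velum, glottis, pharynx).
  The mixture is correlation-preserving — `coupling` is the feature-space
  correlation with the articulator-driven part — and strictly zero-lag
  (frame k of the output depends only on frame k of the input). An
  important design point: the independent channels are gesture-structured
  (still between events), not continuously drifting noise; a continuously
  moving independent component would dominate the frame-to-frame change of
  the mixture and erase co-modulation at any coupling level, which is not
  how unmodeled articulators behave.
- **Timing**: syllable rate defaults to 4.9 Hz with ±10% per-speaker
  jitter and 15% log-normal duration jitter; durations scale with coda
  complexity. Setting `duration_jitter = 0` with all-CV syllables yields
  strictly periodic utterances for period-recovery experiments.
- **Reproducibility**: all randomness flows from one base seed through a
  per-speaker splitting scheme.

What it does **not** emulate: real vocal-tract acoustics (the optional
`render_audio_stream()` produces amplitude-modulated tones, enough to
exercise the cepstral front-end but not speech), pauses and disfluencies,
onset-cluster effects, prosodic slowing near boundaries, or speaker
anatomy. Passing tests on synthetic corpora therefore demonstrates that
the estimators recover known structure under realistic noise and timing
variability — not that any particular empirical effect size holds in real
speech.

## Experiment sizes used by the test suite

The packaged checks run at desk scale, chosen to balance statistical
stability against runtime: 20-speaker corpora (~30 syllables, ~6–8 s each)
for surrogate contrasts and window-width orderings; 51 single-speaker
utterances (17 per period, 40 syllables each, full coupling, periodic
timing) for period recovery at 100/130/160 ms; 12 + 8 speakers for the
syllable-tally pattern and the clean CV-only check; 100 random pairs
(length 50–300) for the brute-force correlation oracle.

## Known limitations

- The correlation is linear; co-modulation carried by nonlinear
  dependence is invisible to it (information-theoretic or recurrence
  methods are out of scope here).
- With very sharp kernels (η = 0.8 at 145.6 Hz) the effective window holds
  few samples, so even surrogate pairs show substantial windowed
  correlations; all inference is therefore relative to the surrogate
  level, never against zero.
- The exact stopband of the historical smoothing implementation is not
  recoverable from its usual description; the order-4 forward–backward
  reading is documented and configurable (`order` argument), and analyses
  should not depend on bit-exact filter behavior.
- Audio-derived features use the integer-sample hop closest to one
  kinematic frame, so their frame rate deviates from 145.6 Hz by up to
  ~0.1%; over a 10 s utterance this drift stays below one frame but is
  recorded on the feature matrix for longer material.
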