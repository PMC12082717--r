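---
title: "Personalized preictal characterization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized preictal characterization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Seizure-prediction models that assume a fixed preictal horizon for every
patient have repeatedly disappointed; `preictalr` takes the opposite,
retrospective view: for each individual seizure it asks *when* the EEG
started to look abnormal, *where* on the scalp, and *in which signal
properties*. The operational definition has three parts.

1. **Representation.** After a 0.5–75 Hz zero-phase FIR band-pass, every
   channel is summarized over 6 s windows with a 3 s hop by ten features:
   spectral entropy (bits), Hjorth mobility and complexity, the Higuchi
   fractal dimension, the relative power in the delta, theta, alpha, beta
   and gamma bands, and the detrended-fluctuation (DFA) exponent. All ten
   are amplitude-scale invariant, which makes them robust to gain
   differences between recordings.

2. **Baseline and distance.** A 2 h interictal interval ending 6 h before
   seizure onset is taken as the patient's own reference. Per channel,
   the windowed feature vectors in that interval define a mean `mu` and
   covariance `S`; every window in the 6 h search span before onset gets a
   Mahalanobis distance `d = sqrt((p - mu)' S^-1 (p - mu))`. The
   threshold `L99` is the 99th percentile of the training windows' own
   distances.

3. **The preictal interval.** A contiguous stretch of windows qualifies
   when its *median* distance exceeds `L99` — equivalently, when strictly
   more than half of its windows exceed the threshold — and it lasts at
   least 15 minutes. Because both criteria are threshold-based, any
   strictly increasing transform of the distances (for instance the
   squared form of the quadratic distance) yields the same intervals;
   this is property-tested.

After an interval is found, channels are ranked by how well a
ridge-penalized logistic regression on their ten (z-scored) features
separates preictal from interictal windows, measured by the held-out F1
score on a stratified 20% test split; channels whose F1 strictly exceeds
the 75th percentile of the F1 distribution are reported, and the
coefficient magnitudes of the best channel's model rank the features.

## Numerical and algorithmic choices

Several points are deliberately pinned down where the underlying
definitions leave room:

* **Spectrum convention.** Spectral entropy and band powers use the
  one-sided periodogram *excluding the DC bin*, so both are well defined
  for any non-constant window regardless of its mean. Band-power
  numerators use half-open bands `[f1, f2)` (adjacent bands never
  double-count a bin) and are normalized by the total power inside the
  0.5–75 Hz analysis band — the filter passband — so "fraction of
  spectral energy" remains meaningful after filtering. The delta band is
  specified as 0.4–4 Hz; with the 0.5 Hz filter edge its effective
  support is 0.5–4 Hz.

* **Derivatives.** Hjorth parameters use plain first differences without
  sampling-rate scaling. Mobility is then the per-sample mean frequency
  (`2 sin(w/2)` for a sinusoid at digital frequency `w`); complexity is
  fully rate-invariant.

* **Free parameters.** Higuchi's `k_max` defaults to 8; DFA uses 12
  log-spaced integer scales from 16 samples to a quarter of the window
  (duplicates after rounding removed). Both are configuration keys.

* **Covariance regularization.** Band powers are linearly constrained
  (their sum cannot exceed 1), so the raw interictal covariance is
  near-singular. A ridge of `lambda * trace(S)/10` is added to the
  diagonal, with `lambda` starting at 1e-6 and escalating tenfold until
  the condition number drops below 1e10. In the degenerate limit of
  identical training vectors this still produces a valid model with all
  training distances (and hence `L99`) equal to zero.

* **Percentiles.** `L99` and the channel-selection quantile both use the
  linear-interpolation convention (R's default type 7).

* **Interval search.** The defining criteria say which intervals qualify
  but not which one to report. Among intervals of at least the minimum
  length whose *endpoint windows are themselves above threshold*, the
  scan maximizes the net exceedance count (#windows above `L99` minus
  #below; ties prefer the longer, then the later interval), then verifies
  the median criterion directly on the winner. Two alternatives were
  rejected: reporting the *longest* qualifying interval lets a clean
  elevated block absorb up to its own length in sub-threshold padding
  (the net count stays positive), which biases both edges outward by
  many minutes under the ~1% background exceedance rate; and without the
  endpoint constraint a fully elevated block shorter than 15 minutes
  could be padded up to the duration floor while still passing the
  median test. The implementation is an O(n) prefix-sum scan and is
  asserted equal to an exhaustive O(n^2) subinterval search on seeded
  series. Masked (degenerate) windows count as neither above nor below
  and are excluded from medians.

* **One interval per record.** Detection runs per channel (the
  per-channel distance traces are the primary diagnostic); the reported
  record-level interval is the one on the channel with the largest
  `d50 / L99` ratio, and all per-channel detections are retained. Whether
  the original procedure combined channels before or after detection is
  not derivable from its description; this choice is the main
  reproduction risk for the per-seizure tables and is therefore kept
  isolated behind `detect_preictal()`.

* **Scoring details.** The stated 80/20 split is used with the 80% part
  for training (the text's inverted phrasing is treated as a slip, since
  the split sizes only make sense that way). The split is stratified by
  class so both classes are present on both sides at any prevalence.
  Features are z-scored with *interictal* statistics before the logistic
  fit — without a common scale, ranking features by raw coefficient
  magnitude would be meaningless. The L2 penalty is weak (`C = 1`,
  glmnet ridge with `lambda = 1/(C * n_train)`), which keeps coefficients
  finite even on separable data. Selection reads "strictly above the
  75th percentile" literally, so an all-equal F1 profile selects nothing
  and the pipeline falls back to the single best channel.

## The synthetic-EEG generator

Real overnight scalp EEG with annotated seizures cannot ship with a
package, so every stage is validated against a generator with known
ground truth. Each channel is a weighted sum of five resonator-filtered
white-noise components — one second-order band-pass resonator per
classical EEG band (centers 2, 6, 10.5, 21, 39 Hz; bandwidths 40% of the
band widths) — with per-band RMS amplitudes (10, 6, 5, 3, 1.5 µV)
decaying roughly as 1/f, for a total RMS near 14 µV. Outside the anomaly
the process is strictly stationary, and generation is bit-reproducible
from the spec's seed.

An anomaly crossfades (1 s raised-cosine ramps) a modified resonator bank
in on the affected channels only:

* `spectral_tilt` broadens every resonance by `45% × effect_size` and
  tilts the band weights toward high frequencies (exponent
  `0.015 × effect_size`), holding total power fixed. The spectrum
  flattens, so spectral entropy and Hjorth mobility rise — these two
  features should, and do, surface at the top of the feature ranking,
  which makes the ranking itself an emergent check rather than something
  wired in.
* `band_shift` transfers `25% × effect_size` (capped at 90%) of the
  alpha-band power into theta and migrates the residual alpha peak
  toward the theta center.
* `entropy_drop` narrows all resonances and concentrates power into the
  alpha band, lowering spectral entropy.

The `effect_size` scale was calibrated once, at design time, so that one
unit displaces the targeted features by roughly one interictal standard
deviation (measured over 6 s windows); at `effect_size = 4` nearly all
in-anomaly windows exceed `L99`. What the generator does **not** emulate:
eye-blink/muscle artifacts, sleep-stage nonstationarity, electrode pops,
inter-channel correlation structure, or any physiological detail beyond
second-order spectral statistics. Passing the synthetic recovery suite
therefore demonstrates that the pipeline implements its definitions
correctly and recovers planted structure — not that it would perform
identically on clinical recordings, where the stationary-interictal
assumption is the main vulnerability.

## Problem sizes used by the validation suite

The recovery and specificity checks run the *full* pipeline on
recordings at the protocol scale: 8.1 h seizure onset, 8.2 h duration,
256 Hz — the span needed for a 2 h interictal interval ending 6 h before
onset. Channel counts are kept small as a problem-size choice: 4
channels (one affected) for the 60 recovery runs, 2 for the duration
floor and null-specificity batches (100 runs each). The per-channel
detector's false-positive behavior does not depend on the montage size,
and a 4-channel montage with one affected channel is the smallest
configuration on which the strict 75th-percentile selection rule can
return exactly the affected set. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations at a smaller run
count for a quick, seeded reproduction.

## Known limitations

* The pipeline is retrospective characterization, not an online alarm;
  nothing here addresses prospective prediction latency.
* A single split per channel (as specified) makes individual F1 scores
  noisy at small preictal sample sizes; the seed is recorded so runs are
  reproducible.
* EDF support targets the common clinical layout (16-bit, one-second
  data records, uniform EEG sampling rate); EDF+ annotation streams are
  ignored in favor of sidecar JSON files.
* With fewer than four channels the selection quantile is undefined by
  construction and the report falls back to the best channel.
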