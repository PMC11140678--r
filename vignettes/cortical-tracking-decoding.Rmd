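---
title: "Decoding cortical tracking of spoken-word features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cortical tracking of spoken-word features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cortrack implements a stimulus-reconstruction ("backward") analysis of
evoked sensor responses to spoken words: how well, and at which
stimulus-to-response delays, can the unfolding acoustic content of a sound
be reconstructed from the neural signal that followed it? The package
bundles the stimulus representations, the decoders, the pairwise
evaluation protocol, the group-level permutation statistics, and a forward
simulator that generates two-cohort synthetic data so the complete
analysis is runnable and testable without access to clinical recordings.

## Stimulus representations

Sounds are represented at 10 ms resolution by:

* **Auditory spectrogram** — 128 overlapping bands with log-spaced center
  frequencies from 180 to 7246 Hz. Each 10 ms frame integrates a 16 ms
  Hann-windowed power spectrum pooled through triangular log-frequency
  weights. This is a deliberately simple stand-in for cochlear filterbank
  models: it preserves the band count, frequency range, and frame timing,
  and the filterbank object is pluggable (`auditory_filterbank()` can be
  replaced by any object with `center_freqs` and a `weights()` function).
  Frame `t` covers `[10t, 10t + 16)` ms, with `t = 0` at sound onset;
  the frame count is `ceiling(duration / 10 ms)`.
* **Amplitude envelope** — the across-band mean of the spectrogram, one
  value per frame; computed from the raw (unstandardized) spectrogram and
  standardized afterwards.
* **Frequency spectrum (FFT)** — whole-sound power pooled through the same
  128 bands; non-time-varying.
* **Modulation power spectrum (MPS)** — energy of the log-spectrogram's
  joint spectral/temporal modulations at four scales (0.5, 1, 2, 4
  cycles/octave) and four rates (1, 3, 9, 27 Hz), measured with Gaussian
  filters on the log2 modulation-frequency axis. Upward and downward
  modulation directions are pooled (filters are symmetric in modulation
  sign). The DC bin is assigned the lowest resolvable modulation
  frequency, so temporally constant input loads the slowest rate filter
  rather than disappearing.
* **Phoneme sequences** — per-word phoneme-by-frame matrices with +1 where
  a phoneme is present and -1 elsewhere, at most one active phoneme per
  frame; only phonemes with at least 10 instances across the stimulus set
  are retained as rows. Annotations come in as plain tables
  (`word_id`, `phoneme`, `start_s`, `end_s`).

**Standardization.** All features and responses are z-scored across the
stimulus set: spectrogram and FFT within each band, MPS within each
(scale, rate, band) cell, envelope and each semantic-style feature across
all stimuli, and sensor responses within each (sensor, 10 ms window) cell.
The population standard deviation (divide by *n*) is used, so a
two-stimulus feature with values {1, 3} standardizes exactly to
{-1, +1}. Zero-variance features are centered at 0, their sd recorded as
0, and restored exactly on inversion.

## Decoding models

**Kernel convolution decoder** (`fit_convolution()`): each time-varying
feature channel `f` is reconstructed as

  `s_hat_f(t) = sum_x sum_tau g_f(tau, x) r(t + tau, x)`

with lags `tau` spanning a window of positive stimulus-to-response delays
(the response follows the stimulus; reconstruction of frame `t` uses the
sensor samples recorded `tau` later). Stacking the lagged response rows
into `R`, the ridge estimate has primal form
`G_f = (R'R + lambda_f I)^-1 R'S_f` and the equivalent dual (kernel) form
`G_f = R'(RR' + lambda_f I)^-1 S_f`, which is cheaper when stimuli-times
are fewer than lag-sensor predictors; `method = "auto"` picks by shape,
and the test suite pins their agreement to 1e-8. Each channel is fitted
independently with its own `lambda_f`.

**Penalty selection.** `lambda_f` is chosen from a grid (default
`10^(-3..6)`) by leave-one-*stimulus*-out error: all rows of a held-out
stimulus leave together, because rows within a stimulus are strongly
dependent, and the pooled Gram matrices are downdated rather than rebuilt
(the tests verify this efficient path against explicit refitting). In
`decode_cv()` the default is to select lambda once per participant/model
(`lambda_selection = "global"`); per-training-fold selection is available
(`"per_fold"`) and is the faithful reading of selection "within the
training data", but costs a grid-by-stimuli factor inside every one of
the 946 folds. On the synthetic data the two agree closely because
selection is stable across folds.

**Static dual ridge** (`fit_ridge_static()`): non-time-varying features
(FFT, MPS, semantic-style vectors) are decoded from the flattened
0–1000 ms response window with kernel ridge regression; the
leave-one-out residual uses the closed form `alpha_i / Q_ii`.

**Phoneme logistic decoders** (`fit_logistic_phonemes()`): one binary
ridge-penalized logistic model per retained phoneme on the lagged rows,
trained by minibatch SGD with a decaying learning rate and tail-averaged
iterates (max 200 epochs, loss tolerance 1e-6, seed recorded). A phoneme
is scored active when its predicted probability strictly exceeds 0.5;
phonemes with single-class training labels are skipped with a warning.

**Boundary handling.** Lagged rows that would index outside the epoch are
zero-filled; responses are baseline-corrected toward zero, so zero is the
natural padding value. Internally lags are non-negative sample delays;
all public interfaces use milliseconds.

## Evaluation protocol

Performance is evaluated by leave-two-out cross-validation over all
`C(n, 2)` unordered stimulus pairs (946 for 44 stimuli). For each pair the
model is trained on the remainder, both held-out stimuli are
reconstructed, the two time-varying features are truncated to the length
of the shorter one, and the pair is scored correct when

  `sim(s1, p1) + sim(s2, p2) > sim(s1, p2) + sim(s2, p1)`

with `sim` the Pearson correlation over all flattened (channel, frame)
cells — a single similarity per pair, rather than per-band averages. Exact
ties score 0.5 (they have probability zero in continuous data but matter
in degenerate tests); zero-variance vectors get similarity 0 with a
warning. Accuracy is the percentage of correct pairs.

Standardization is computed on the full stimulus set before
cross-validation, replicating the published protocol; `strict = TRUE`
re-estimates it within each training fold for leakage sensitivity checks.
The leakage is real but subtle: with per-cell response standardization
over *n* stimuli, the held-out epoch is a deterministic function of the
training epochs' cells, which is visible in pure-noise checks (the test
suite bypasses standardization there).

`loo_reconstruction()` complements the pairwise criterion with
leave-one-out reconstruction correlations; on synthetic cohorts the two
protocols rank participants consistently.

**SNR.** `estimate_snr()` z-scores each sensor's epoch by its baseline
mean/sd and reports the mean squared standardized intensity during
stimulus presentation divided by the baseline variance of the z-scored
signal, averaged over sensors and stimuli. The wording this operationalizes
is ambiguous; this reading has the property that pure noise gives values
near 1 and that amplitude scaling increases it monotonically, which is
what the tests pin down.

## Group statistics

* `permutation_test()` builds per-participant nulls by shuffling the
  stimulus labels of the evoked responses (within stimulus class when
  given) and re-running the full leave-two-out evaluation; the p-value is
  the fraction of permutations strictly better than the observed accuracy
  (an add-one convention is available but off by default), and the
  alpha = 0.05 threshold is the null's 95th percentile. By default the
  penalty selected on the observed pairing is reused across permutations
  (`lambda_mode = "observed"`); full re-selection (`"refit"`) gives
  near-identical nulls on synthetic data because selection is stable.
* `lag_sweep()` advances a 20-ms-wide lag window in non-overlapping steps
  (20–40 … 400–420 ms), one full evaluation per window.
* `group_compare()` runs pooled-variance independent-samples t tests
  (Welch optional; the pooled flavor matches df = 32 for 17 + 17),
  Benjamini–Hochberg FDR at 0.05, and Cohen's d with the pooled sd.
* `cluster_permutation()` thresholds per-lag t statistics at the
  cluster-forming alpha (default 0.05, two-sided; one-sided available),
  forms contiguous same-sign clusters, sums t within each, selects the
  largest mass, and compares it against a null built by randomly
  reassigning participants to groups of the original sizes with the same
  largest-cluster rule; `p = N(null mass > observed mass) / N`. With no
  supra-threshold lag the result is an empty cluster table with p = 1.

## The forward simulator

`simulate_cohort()` generates the full study design: a shared set of 44
syllable-structured stimuli, two cohorts of 17 participants, 56 sensor
channels (emulating 28 bilateral planar gradiometer pairs) at 100 Hz,
20-trial-averaged epochs with a 300 ms baseline.

* **Stimuli**: 2–5 syllable-like amplitude bursts (word-initial burst
  stressed, as in fixed-initial-stress languages) with smooth random
  two-bump spectral profiles; durations from N(810, 180^2) ms truncated to
  [400, 1400] ms; the syllable count distribution (45/35/15/5% for 2–5)
  puts the mean near 2.8 syllables so that typical syllable spacing is
  near 300 ms.
* **Response functions**: a Gabor-shaped early component centered at
  100 ms (width 40 ms, 10 Hz carrier) and a broad raised-cosine late
  component spanning 160–340 ms, each with a fixed random sensor
  topography per participant (unit RMS per sensor, so signal amplitude
  does not dilute with sensor count). The DLD-like group's late gain is
  scaled by `deficit_factor` in [0, 1]; `deficit_factor = 1` makes the
  groups statistically exchangeable. The latent effect size of the real
  late-lag deficit is unknown, so `deficit_factor` is a free simulation
  parameter, not an estimate.
* **Forward model**: responses are the standardized amplitude envelope
  convolved with the response function plus i.i.d. Gaussian noise of sd
  `noise_sd / sqrt(trial_count)`, emulating a 20-trial average. All child
  seeds derive deterministically from the master seed.

**Choosing the noise level.** With white sensor noise the two natural
realism targets are incompatible: matching the reported channel-level SNR
(~18) leaves decoding saturated at 100% everywhere, because i.i.d. noise
is averaged away by the high-dimensional ridge, while matching the
published lag-curve range requires per-cell SNR near 1. The default
(`noise_sd = 60` per trial) targets the decoding side: 20-ms-window lag
curves peak well above chance near the early component and fall toward
chance at uninformative lags, which is the regime the statistical
machinery (peak localization, cluster power and calibration) actually
exercises. Real evoked data additionally contain stimulus-locked activity
that does not track the envelope, temporally and spatially correlated
noise, and nonlinearities — none of which the simulator emulates — so
passing tests demonstrate correctness of the pipeline under its own
forward model, not performance claims about real MEG.

A second consequence of the simple generator is worth knowing: because
the stimuli share a ~300 ms syllable rhythm, lag windows near the
syllable period decode above chance through envelope autocorrelation even
when the response function has no support there. This mirrors a genuine
property of lagged decoding of rhythmic stimuli and is visible in the
simulated lag curves.

## Problem sizes and numerical choices

The replicated simulations in the test suite and the acceptance script
use desk-scale analysis dimensions chosen once: 4–8 sensor channels,
8–44 stimuli, penalty fixed at the mid-grid value (lambda = 100) inside
replicated lag sweeps, 500 permutations per cluster test, and cohorts of
2 x 6 (calibration) or 2 x 17 (power) participants. The permutation-null
significance thresholds are properties of the pairwise criterion and the
stimulus-set size, and are insensitive to the sensor dimension, which is
why the threshold targets are computed at 4 channels. Ties in the
accuracy grid are handled by the 0.5 scoring rule; singular ridge systems
at a grid point are skipped with a warning.

## Known limitations

* The cluster-permutation p-value is discrete and conservative by
  construction: with a two-sided cluster-forming threshold at alpha = 0.05
  over 20 lag windows, roughly a 0.95^20 ≈ 0.36 fraction of null data
  sets produce no cluster at all and receive p = 1. The p-value
  distribution under exchangeability therefore has a large atom at 1 and
  cannot be uniform in the Kolmogorov–Smirnov sense, although it remains
  valid (P(p <= alpha) <= alpha up to Monte Carlo error), which is what
  the property tests assert.
* The 8-item significance threshold is driven by item-level heterogeneity
  (notably duration spread) of the generated stimuli and lands a few
  points above what a homogeneous pseudoword set yields; small-set
  thresholds should be read as set-specific, which is exactly why the
  protocol computes them per stimulus set by permutation.
* Full-set standardization before cross-validation leaks a small amount
  of held-out information by construction; `strict = TRUE` quantifies it.
* The filterbank is a spectral-domain approximation of cochlear models;
  absolute band energies differ from cochleagram toolboxes even though
  band placement and frame timing match.
* Semantic norms are out of scope; synthetic fixed-length vectors stand
  in wherever a semantic feature set is needed.
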