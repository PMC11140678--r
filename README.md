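# cortrack

Decoding cortical tracking of spoken-word features from evoked MEG-style
sensor responses.

## The problem

When a spoken word unfolds, auditory cortex produces activity that is
time-locked to the acoustic stream: each moment of the sound is followed,
some 100 ms later, by a neural response that carries enough information to
reconstruct the sound's amplitude envelope and spectrogram. How long that
information persists — whether the sound at time *t* can still be read out
of the response at *t* + 300 ms — speaks to the maintenance of
acoustic–phonetic information in short-term memory, and is a candidate
mechanism for developmental language disorder (DLD), where that late
maintenance appears selectively weakened.

cortrack is for researchers who want to run, extend, or stress-test this
*stimulus-reconstruction* (backward-modeling) analysis: it implements the
feature extraction, the decoders, the evaluation protocol, the group
statistics, and a forward simulator that produces two-cohort synthetic
data sets with a controllable late-lag deficit, so every stage of the
pipeline can be exercised and validated without access to clinical
recordings.

## The model

The core decoder is a kernel (dual) ridge convolution model. For each
feature channel *f* (e.g. the amplitude envelope, or one spectrogram
band), the time-varying feature is reconstructed from lagged sensor
samples,

    ŝ_f(t) = Σ_x Σ_τ g_f(τ, x) · r(t + τ, x),     τ ∈ [τ₁, τ₂], τ ≥ 0,

where `r(t, x)` is the evoked response at sensor *x* and `g_f` is a
spatiotemporal response function estimated by ridge regression in its
dual form,

    Ĝ_f = R'(RR' + λ_f I)⁻¹ S_f,

with `R` the lagged design matrix and `λ_f` chosen per channel on a grid
by leave-one-stimulus-out error. Static features (frequency spectrum,
modulation power spectrum, semantic-style vectors) use the analogous dual
ridge on the flattened 0–1000 ms window; phoneme sequences use one binary
logistic decoder per phoneme.

Decoding is scored by leave-two-out pairwise classification: for every
pair of stimuli the model is trained on the rest, both held-out stimuli
are reconstructed, and the pair counts correct when

    sim(s₁, p₁) + sim(s₂, p₂) > sim(s₁, p₂) + sim(s₂, p₁),

with `sim` the Pearson correlation (44 stimuli → 946 pairwise tests;
chance = 50%). Per-participant significance comes from stimulus-label
permutation nulls; group differences in lag-resolved decoding curves are
tested with cluster-based permutation over 20-ms lag windows (largest
cluster mass, group-relabeling null).

## Worked example

Simulate a small two-cohort experiment in which the DLD-like group's late
(160–340 ms) response component is scaled to 0.3, decode one participant,
and test the group difference across lags:

```r
library(cortrack)

spec   <- cohort_spec(n_per_group = 6, n_stimuli = 12, n_sensors = 6, seed = 1)
cohort <- simulate_cohort(spec, deficit_factor = 0.3)
cohort
#> Synthetic cohort: 6 TD-like + 6 DLD-like participants, 12 stimuli,
#>   deficit factor 0.30, noise sd 60.00

p1  <- cohort$participants[[1]]
res <- decode_cv(p1$evoked, cohort$drive, model = "convolution",
                 lag_ms = c(20, 420))
summary(res)
#> Model: convolution decoder, lag window 20-420 ms
#> Accuracy: 98.48% over 66 pairwise tests (chance 50%)
#> Ridge penalty: 1000

permutation_test(p1$evoked, cohort$drive, n_permutations = 100,
                 lambda = res$lambda, seed = 1)
#> Label-permutation test (convolution model, 100 permutations)
#>   observed 98.5%, null mean 51.5%, 95th pct 71.3%, p = 0

curves <- t(sapply(cohort$participants, function(p)
  lag_sweep(p$evoked, cohort$drive, lambda = 100)$accuracy))
cluster_permutation(curves, cohort$groups, n_permutations = 1000,
                    windows = data.frame(start_ms = seq(20, 400, 20),
                                         end_ms   = seq(40, 420, 20)))
#> Cluster permutation test (two.sided, 1000 permutations)
#>   largest cluster 180-320 ms (TD > DLD), mass 26.67, p = 0
```

Reading the output: the wide-window (20–420 ms) convolution decoder
reconstructs the envelope well enough to identify the correct stimulus in
98.5% of the 66 pairwise tests, far above this participant's permutation
threshold (71.3% for a 12-item set). Sweeping a 20-ms lag window across
20–420 ms and comparing the two groups recovers the implanted deficit:
the largest TD > DLD cluster spans 180–320 ms — inside the constructed
160–340 ms late component — with a group-relabeling p-value below 1/1000.

A command-line wrapper over the same functions lives in
`inst/cli/cortrack.R`:

```sh
Rscript inst/cli/cortrack.R simulate --seed 1 --out run1 --n-per-group 6 --n-stimuli 12 --n-sensors 6
Rscript inst/cli/cortrack.R lagsweep --data run1 --out run1/curves.tsv
Rscript inst/cli/cortrack.R stats    --curves run1/curves.tsv --out run1/cluster.json
```

## Package layout

| Area | Files | Entry points |
| --- | --- | --- |
| Stimulus features | `R/filterbank.R`, `R/features.R`, `R/standardize.R` | `compute_spectrogram()`, `compute_envelope()`, `compute_fft_spectrum()`, `compute_mps()`, `encode_phonemes()`, `standardize_features()` |
| Forward simulator | `R/synthetic.R` | `cohort_spec()`, `synth_stimuli()`, `response_function()`, `simulate_evoked()`, `simulate_cohort()` |
| Decoders | `R/design.R`, `R/ridge.R`, `R/logistic.R` | `lagged_design()`, `fit_convolution()`, `fit_ridge_static()`, `fit_logistic_phonemes()` |
| Evaluation | `R/evaluate.R` | `decode_cv()`, `loo_reconstruction()`, `classify_pair()`, `estimate_snr()` |
| Statistics | `R/stats.R` | `permutation_test()`, `lag_sweep()`, `group_compare()`, `cluster_permutation()` |
| IO / CLI | `R/io.R`, `R/cli.R` | `read_wav()`, `read_evoked()`, `read_config()`, `cli_main()` |

The methods vignette
(`vignettes/cortical-tracking-decoding.Rmd`) documents the models, the
simulator's assumptions, the numerical choices, and known limitations.
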