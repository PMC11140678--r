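#' Cohort specification for the forward simulator
#'
#' Collects the study-design constants of a simulated two-cohort
#' experiment: two groups of 17 participants listening to a shared set of
#' 44 syllable-structured sounds, with trial-averaged (20 repetitions)
#' evoked responses sampled at 100 Hz over 56 sensor channels (emulating
#' 28 bilateral planar gradiometer pairs).
#'
#' @param n_per_group participants per group (default 17).
#' @param n_stimuli stimuli in the shared set (default 44).
#' @param n_sensors sensor channels (default 56).
#' @param rate response sampling rate in Hz (default 100).
#' @param trial_count trials averaged per evoked response (default 20).
#' @param n_bands spectrogram bands in the synthetic stimuli (default 32).
#' @param baseline_ms pre-stimulus baseline per epoch (default 300).
#' @param lag_max_ms response-function support in ms (default 420).
#' @param seed master seed; all child seeds derive from it.
#' @return object of class `ct_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 17L, n_stimuli = 44L, n_sensors = 56L,
                        rate = 100, trial_count = 20L, n_bands = 32L,
                        baseline_ms = 300, lag_max_ms = 420, seed = 1L) {
  counts <- c(n_per_group, n_stimuli, n_sensors, trial_count, n_bands)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_stimuli = as.integer(n_stimuli),
                 n_sensors = as.integer(n_sensors), rate = rate,
                 trial_count = as.integer(trial_count),
                 n_bands = as.integer(n_bands), baseline_ms = baseline_ms,
                 lag_max_ms = lag_max_ms, seed = as.integer(seed)),
            class = "ct_cohort_spec")
}

#' @export
print.ct_cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("Cohort spec: 2 x %d participants, %d stimuli, %d sensors",
                     " @ %g Hz, %d trials/stimulus, seed %d\n"),
              x$n_per_group, x$n_stimuli, x$n_sensors, x$rate,
              x$trial_count, x$seed))
  invisible(x)
}

#' Generate a synthetic stimulus set
#'
#' Builds spectrogram-level representations of syllable-structured sounds:
#' each stimulus is 2-5 syllable-like amplitude bursts (word-initial burst
#' stressed, as in fixed-initial-stress languages) with smooth random
#' spectral profiles, durations drawn from N(810, 180^2) ms truncated to
#' [400, 1400] ms. Envelopes are derived with [compute_envelope()].
#'
#' @param spec a [cohort_spec()].
#' @param seed seed (defaults to the spec's master seed).
#' @return object of class `ct_stimuli`: `spectrograms` (list of
#'   band x frame matrices), `envelopes` (list of per-frame vectors),
#'   `n_frames`, `syllables`, `frame_step` (0.01 s), `ids`.
#' @export
synth_stimuli <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ct_cohort_spec"))
  set.seed(seed)
  n <- spec$n_stimuli
  nb <- spec$n_bands
  frame_step <- 1 / spec$rate
  dur <- numeric(n)
  for (i in seq_len(n)) {
    repeat { d <- stats::rnorm(1, 810, 180); if (d >= 400 && d <= 1400) break }
    dur[i] <- d
  }
  Tn <- pmax(10L, as.integer(round(dur / (1000 * frame_step))))
  syl <- sample(2:5, n, replace = TRUE, prob = c(0.45, 0.35, 0.15, 0.05))
  band_axis <- seq(0, 1, length.out = nb)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    M <- matrix(0, nb, Tn[i])
    k <- syl[i]
    span <- Tn[i] / k
    for (j in seq_len(k)) {
      onset <- (j - 1) * span + stats::runif(1, -0.08, 0.08) * span
      width <- stats::runif(1, 0.55, 0.9) * span
      amp <- stats::runif(1, 0.5, 1) * if (j == 1L) 1.4 else 1
      t0 <- seq_len(Tn[i])
      u <- (t0 - 1 - onset) / width
      env <- ifelse(u >= 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
      # smooth random spectral profile: two formant-like bumps
      c1 <- stats::runif(1, 0.05, 0.5); c2 <- stats::runif(1, 0.4, 0.95)
      w1 <- stats::runif(1, 0.05, 0.2); w2 <- stats::runif(1, 0.1, 0.3)
      prof <- exp(-(band_axis - c1)^2 / (2 * w1^2)) +
        0.6 * exp(-(band_axis - c2)^2 / (2 * w2^2))
      M <- M + amp * outer(prof, env)
    }
    specs[[i]] <- M + 1e-3
  }
  envs <- lapply(specs, function(M) compute_envelope(M)$values)
  structure(list(spectrograms = specs, envelopes = envs, n_frames = Tn,
                 syllables = syl, frame_step = frame_step,
                 ids = paste0("S", seq_len(n))),
            class = "ct_stimuli")
}

#' @export
print.ct_stimuli <- function(x, ...) {
  cat(sprintf("Synthetic stimuli: %d items, %d bands, %d-%d frames (10 ms)\n",
              length(x$spectrograms), nrow(x$spectrograms[[1L]]),
              min(x$n_frames), max(x$n_frames)))
  invisible(x)
}

#' Synthetic semantic feature vectors
#'
#' Real semantic norms (questionnaire features, corpus co-occurrence
#' statistics) are study-specific assets; this generator substitutes
#' fixed-length random vectors with a block-category structure: stimuli in
#' the same category share a common prototype plus item-specific
#' variation, which is enough to exercise the static-feature decoder.
#'
#' @param n_stimuli number of stimuli.
#' @param n_features vector length per stimulus (default 50).
#' @param n_categories prototype clusters (default 6).
#' @param seed seed.
#' @return `n_stimuli x n_features` matrix; rows are stimuli.
#' @export
synth_semantic <- function(n_stimuli, n_features = 50L, n_categories = 6L,
                           seed = 1L) {
  set.seed(seed)
  proto <- matrix(stats::rnorm(n_categories * n_features), n_categories)
  cat_of <- sort(rep_len(seq_len(n_categories), n_stimuli))
  proto[cat_of, , drop = FALSE] +
    matrix(stats::rnorm(n_stimuli * n_features, sd = 0.5), n_stimuli)
}

#' Ground-truth spatiotemporal response function
#'
#' Builds the lag x channel x sensor weight array g(tau, f, x) used by the
#' forward simulator: a Gabor-shaped early component centered at ~100 ms
#' (width 40 ms) plus a broad late component spanning 160-340 ms, each
#' with its own fixed random sensor topography. Weights are zero outside
#' 0-`lag_max_ms`; both temporal kernels and topographies are normalized
#' to unit L2 norm, so `early_gain`/`late_gain` set component amplitudes
#' directly.
#'
#' @param n_sensors number of sensor channels.
#' @param n_channels driving feature channels (default 1, the envelope).
#' @param rate sampling rate in Hz (default 100).
#' @param lag_max_ms kernel support end in ms (default 420).
#' @param early_gain,late_gain component amplitudes (`late_gain >= 0`).
#' @param early_center_ms,early_width_ms Gabor center and envelope width.
#' @param late_window_ms late component support (default `c(160, 340)`).
#' @param seed seed for the topographies.
#' @return object of class `ct_rf`: `weights` (lag x channel x sensor),
#'   `lags_ms`, `rate`, gains and windows.
#' @export
response_function <- function(n_sensors, n_channels = 1L, rate = 100,
                              lag_max_ms = 420, early_gain = 1,
                              late_gain = 0.6, early_center_ms = 100,
                              early_width_ms = 40,
                              late_window_ms = c(160, 340), seed = 1L) {
  if (late_gain < 0) stop("late_gain must be >= 0", call. = FALSE)
  set.seed(seed)
  lags_ms <- seq(0, lag_max_ms, by = 1000 / rate)
  sig <- early_width_ms / 2
  early <- exp(-(lags_ms - early_center_ms)^2 / (2 * sig^2)) *
    cos(2 * pi * (lags_ms - early_center_ms) / 100)
  mid <- mean(late_window_ms); half <- diff(late_window_ms) / 2
  late <- ifelse(abs(lags_ms - mid) <= half,
                 0.5 * (1 + cos(pi * (lags_ms - mid) / half)), 0)
  early <- early / sqrt(sum(early^2))
  late <- late / sqrt(sum(late^2))
  # unit RMS per element, so per-sensor signal amplitude does not dilute
  # as the sensor count grows
  unitvec <- function(k) { v <- stats::rnorm(k); v / sqrt(mean(v^2)) }
  topo_e <- unitvec(n_sensors); topo_l <- unitvec(n_sensors)
  load_e <- if (n_channels == 1L) 1 else unitvec(n_channels)
  load_l <- if (n_channels == 1L) 1 else unitvec(n_channels)
  W <- array(0, dim = c(length(lags_ms), n_channels, n_sensors))
  for (f in seq_len(n_channels)) {
    W[, f, ] <- early_gain * load_e[f] * outer(early, topo_e) +
      late_gain * load_l[f] * outer(late, topo_l)
  }
  structure(list(weights = W, lags_ms = lags_ms, rate = rate,
                 early_gain = early_gain, late_gain = late_gain,
                 late_window_ms = late_window_ms, seed = seed),
            class = "ct_rf")
}

#' Simulate evoked responses by forward convolution
#'
#' Generates trial-averaged sensor responses
#' `r(t, x) = sum_f sum_tau g(tau, f, x) s_f(t - tau) + eps`, with
#' `eps ~ N(0, noise_sd^2 / trial_count)` i.i.d. emulating a
#' `trial_count`-trial average, plus a silent pre-stimulus baseline
#' carrying only noise. Each response extends `lag_max` samples past the
#' end of its stimulus; all epochs share the longest time axis.
#'
#' @param drive driving features: list (one per stimulus) of
#'   channels x frames matrices or numeric vectors (single channel).
#' @param rf a [response_function()] with matching channel count and rate.
#' @param noise_sd per-trial sensor noise sd (0 for noise-free).
#' @param trial_count trials in the average (default 20).
#' @param rate driving feature rate in Hz; must equal `rf$rate`.
#' @param baseline_frames pre-onset noise-only samples (default 30,
#'   i.e. 300 ms at 100 Hz).
#' @param seed seed for the noise.
#' @return a [evoked_set()] whose `lengths` are the stimulus frame counts.
#' @export
simulate_evoked <- function(drive, rf, noise_sd = 0, trial_count = 20L,
                            rate = 100, baseline_frames = 30L, seed = 1L) {
  stopifnot(inherits(rf, "ct_rf"))
  if (rate != rf$rate)
    stop("sampling rate of features and response function differ", call. = FALSE)
  drive <- lapply(drive, as_channel_matrix)
  nc <- dim(rf$weights)[2L]
  if (nrow(drive[[1L]]) != nc)
    stop("driving channel count does not match response function", call. = FALSE)
  L <- dim(rf$weights)[1L]
  ns <- dim(rf$weights)[3L]
  Tn <- vapply(drive, ncol, 1L)
  post <- max(Tn) + L - 1L
  ntime <- baseline_frames + post
  set.seed(seed)
  out <- array(0, dim = c(length(drive), ns, ntime))
  for (i in seq_along(drive)) {
    len <- Tn[i] + L - 1L
    sig <- matrix(0, len, ns)
    for (f in seq_len(nc)) {
      d <- drive[[i]][f, ]
      # lagged copies of the drive: column tau holds s_f(t - tau)
      E <- matrix(0, len, L)
      for (l in seq_len(L)) E[(l:(l + Tn[i] - 1L)), l] <- d
      sig <- sig + E %*% rf$weights[, f, ]
    }
    out[i, , (baseline_frames + 1L):(baseline_frames + len)] <- t(sig)
  }
  if (noise_sd > 0)
    out <- out + stats::rnorm(length(out), 0, noise_sd / sqrt(trial_count))
  evoked_set(out, rate = rate, onset = baseline_frames + 1L,
             lengths = Tn)
}

#' Simulate a two-cohort experiment
#'
#' Generates a shared synthetic stimulus set and per-participant evoked
#' responses for a typically-developing-like ("TD") and a language-
#' disorder-like ("DLD") cohort. Both groups share the early ~100 ms
#' response component; the DLD-like group's late (160-340 ms) component is
#' scaled by `deficit_factor`. Sensor topographies are random but fixed
#' per participant; all child seeds derive deterministically from the
#' master seed.
#'
#' @param spec a [cohort_spec()].
#' @param deficit_factor late-component scaling for the DLD-like group,
#'   in [0, 1] (1 = groups generated identically).
#' @param noise_sd per-trial sensor noise sd (default 60). With the
#'   default 20-trial average this leaves an effective white noise sd of
#'   ~13 against unit-RMS signal components, chosen so that lag-resolved
#'   decoding curves span the informative range (peaks well above chance
#'   in 20 ms windows, tails near chance) rather than saturating; see the
#'   methods vignette for the trade-off against the channel-level SNR
#'   statistic under white noise.
#' @param early_gain,late_gain TD-group component amplitudes.
#' @param seed master seed (defaults to the spec's).
#' @return object of class `ct_cohort`: `spec`, `stimuli`, `drive` (the
#'   standardized envelopes driving the forward model), `participants`
#'   (list with `id`, `group`, `rf`, `evoked`, `seed`), `groups` factor.
#' @export
simulate_cohort <- function(spec, deficit_factor = 0.5, noise_sd = 60,
                            early_gain = 1, late_gain = 0.6,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "ct_cohort_spec"))
  if (deficit_factor < 0 || deficit_factor > 1)
    stop("deficit_factor must lie in [0, 1]", call. = FALSE)
  stim <- synth_stimuli(spec, seed = seed)
  drive <- standardize_features(stim$envelopes)$x
  set.seed(seed + 1L)
  n <- spec$n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, 4L * n)
  groups <- rep(c("TD", "DLD"), each = n)
  participants <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    lg <- late_gain * if (groups[i] == "DLD") deficit_factor else 1
    rf <- response_function(spec$n_sensors, rate = spec$rate,
                            lag_max_ms = spec$lag_max_ms,
                            early_gain = early_gain, late_gain = lg,
                            seed = seeds[2L * i - 1L])
    ev <- simulate_evoked(drive, rf, noise_sd = noise_sd,
                          trial_count = spec$trial_count, rate = spec$rate,
                          baseline_frames = round(spec$baseline_ms / 1000 * spec$rate),
                          seed = seeds[2L * i])
    participants[[i]] <- list(id = sprintf("P%02d", i), group = groups[i],
                              rf = rf, evoked = ev, seed = seeds[2L * i - 1L])
  }
  structure(list(spec = spec, stimuli = stim, drive = drive,
                 participants = participants,
                 groups = factor(groups, levels = c("TD", "DLD")),
                 deficit_factor = deficit_factor, noise_sd = noise_sd),
            class = "ct_cohort")
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d TD-like + %d DLD-like participants, ",
                     "%d stimuli, deficit factor %.2f, noise sd %.2f\n"),
              sum(x$groups == "TD"), sum(x$groups == "DLD"),
              x$spec$n_stimuli, x$deficit_factor, x$noise_sd))
  invisible(x)
}
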