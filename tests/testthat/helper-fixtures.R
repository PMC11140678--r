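# Shared fixture builders. Everything is generated in code at test time.

tone_wave <- function(freq = 1000, dur = 0.5, rate = 16000) {
  waveform(sin(2 * pi * freq * seq(0, dur, by = 1 / rate)), rate = rate)
}

# small random evoked set: n stimuli x ns sensors, per-stimulus lengths Tn,
# epoch padded with `pad` extra post-onset samples and a short baseline
rand_evoked <- function(n = 4, ns = 2, Tn = rep(6, n), pad = 5, onset = 3,
                        seed = 1) {
  set.seed(seed)
  ntime <- onset - 1 + max(Tn) + pad
  evoked_set(array(rnorm(n * ns * ntime), c(n, ns, ntime)),
             onset = onset, lengths = Tn)
}

# brute-force lagged design row constructor (independent of the package's
# vectorized implementation): frame t of stimulus n uses r(t + lag, x),
# zero outside the epoch, columns lag-major
brute_lagged <- function(evoked, lag_ms) {
  rate <- evoked$rate
  lags <- as.integer(round(lag_ms[1] / 1000 * rate)):as.integer(round(lag_ms[2] / 1000 * rate))
  ns <- dim(evoked$data)[2]
  nt <- dim(evoked$data)[3]
  lapply(seq_along(evoked$lengths), function(n) {
    Tn <- evoked$lengths[n]
    X <- matrix(0, Tn, length(lags) * ns)
    for (t in seq_len(Tn)) {
      for (j in seq_along(lags)) {
        for (x in seq_len(ns)) {
          src <- evoked$onset + (t - 1) + lags[j]
          X[t, (j - 1) * ns + x] <-
            if (src >= 1 && src <= nt) evoked$data[n, x, src] else 0
        }
      }
    }
    X
  })
}

# explicit refit-and-predict leave-one-stimulus-out error (oracle for the
# efficient downdated LOO): returns |grid| x channels error matrix
explicit_conv_loo <- function(design, S, grid) {
  S <- lapply(S, function(s) if (is.matrix(s)) s else matrix(s, nrow = 1))
  nf <- nrow(S[[1]])
  n <- length(design$blocks)
  err <- matrix(0, length(grid), nf)
  for (gi in seq_along(grid)) {
    for (g in seq_len(n)) {
      keep <- setdiff(seq_len(n), g)
      sub <- design
      sub$blocks <- design$blocks[keep]
      fit <- fit_convolution(sub, S[keep], lambda = grid[gi])
      pred <- t(design$blocks[[g]] %*% fit$G)
      err[gi, ] <- err[gi, ] + rowSums((S[[g]] - pred)^2)
    }
  }
  err
}

# tiny deterministic cohort for pipeline tests
tiny_cohort <- function(n_per_group = 2, n_stimuli = 6, n_sensors = 4,
                        seed = 42, deficit = 0.5, noise = 60) {
  simulate_cohort(cohort_spec(n_per_group = n_per_group,
                              n_stimuli = n_stimuli, n_sensors = n_sensors,
                              seed = seed),
                  deficit_factor = deficit, noise_sd = noise)
}
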