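test_that("spectrogram localizes a pure tone and obeys frame arithmetic", {
  fb <- auditory_filterbank()
  s <- compute_spectrogram(tone_wave(1000, 0.5), fb)
  expect_equal(nrow(s$values), 128L)
  # frame count = ceiling(duration / 10 ms)
  expect_equal(ncol(s$values), ceiling(0.5 * 16000 / 160) + 1L)  # 0.5 s + 1 sample
  # energy concentrated in bands bracketing 1 kHz
  peak_band <- which.max(rowMeans(s$values))
  expect_lt(abs(log(fb$center_freqs[peak_band] / 1000)), 0.1)
  # near-constant over interior frames
  interior <- s$values[peak_band, 3:(ncol(s$values) - 3)]
  expect_lt(stats::sd(interior) / mean(interior), 0.05)

  # an 810 ms sound at 10 ms frames has 81 frames
  w810 <- waveform(rnorm(0.81 * 16000))
  expect_equal(ncol(compute_spectrogram(w810)$values), 81L)
})

test_that("spectrogram handles silence, scaling, and bad input", {
  zero <- waveform(numeric(1600))
  expect_true(all(compute_spectrogram(zero)$values == 0))
  w <- waveform(rnorm(4000))
  s1 <- compute_spectrogram(w)$values
  s2 <- compute_spectrogram(waveform(2 * w$samples))$values
  expect_true(all(s2 >= s1))                     # energy monotone in amplitude
  expect_error(waveform(numeric(0)), "empty")
  expect_error(waveform(c(1, NA)), "non-finite")
  expect_error(compute_spectrogram(waveform(rnorm(10))), "shorter")
})

test_that("envelope is the exact across-band spectrogram mean", {
  w <- waveform(rnorm(3200))
  s <- compute_spectrogram(w)
  expect_identical(compute_envelope(s)$values, colMeans(s$values))
  expect_equal(compute_envelope(rbind(c(1, 3), c(3, 5)))$values, c(2, 4))
  v <- rnorm(7)
  expect_equal(compute_envelope(matrix(rep(v, each = 5), 5))$values, v)
  expect_true(all(compute_envelope(matrix(0, 4, 6))$values == 0))
})

test_that("FFT band spectrum localizes tones and is reversal-invariant", {
  fb <- auditory_filterbank()
  f <- compute_fft_spectrum(tone_wave(2000, 0.4), fb)
  expect_length(f$values, 128L)
  expect_true(all(f$values >= 0))
  expect_lt(abs(log(fb$center_freqs[which.max(f$values)] / 2000)), 0.1)
  w <- waveform(rnorm(3000))
  f1 <- compute_fft_spectrum(w)$values
  f2 <- compute_fft_spectrum(waveform(rev(w$samples)))$values
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_true(all(compute_fft_spectrum(waveform(numeric(800)))$values == 0))
})

test_that("modulation power spectrum picks out temporal rates", {
  fb <- auditory_filterbank(n_bands = 32)
  mk <- function(vals) {
    structure(list(values = vals, center_freqs = fb$center_freqs,
                   frame_step = 0.01, integration_window = 0.016),
              class = "ct_spectrogram")
  }
  # band-varying but temporally constant -> energy at the lowest rate
  prof <- exp(-((1:32) - 12)^2 / 40)
  m <- compute_mps(mk(matrix(prof, 32, 120)))
  rate_marginal <- apply(m$values, 2, sum)
  expect_equal(which.max(rate_marginal), 1L)
  expect_equal(dim(m$values), c(4L, 4L, 32L))
  # 9 Hz amplitude modulation across all bands -> peak at the 9 Hz filter
  t <- seq_len(120)
  am <- 1.5 + sin(2 * pi * 9 * t * 0.01)
  m9 <- compute_mps(mk(matrix(rep(am, each = 32), 32)))
  expect_equal(which.max(apply(m9$values, 2, sum)), 3L)
  # all-zero spectrogram -> all-zero array
  expect_true(all(compute_mps(mk(matrix(0, 32, 120)))$values == 0))
  # fewer frames than slowest filter support -> warning, zero-padded
  expect_warning(compute_mps(mk(matrix(runif(32 * 50), 32))), "zero-padding")
})

test_that("phoneme encoding follows the +/-1 frame convention", {
  ann <- data.frame(word_id = "aa", phoneme = "a", start_s = 0, end_s = 0.2)
  # pad the set so /a/ reaches the instance threshold
  filler <- data.frame(word_id = paste0("w", 1:9), phoneme = "a",
                       start_s = 0, end_s = 0.1)
  ph <- encode_phonemes(rbind(ann, filler), min_count = 10)
  expect_equal(ph$labels, "a")
  M <- ph$matrices[["aa"]]
  expect_equal(ncol(M), 20L)
  expect_true(all(M["a", ] == 1))

  # a phoneme with 9 instances is excluded at min_count = 10
  nine <- data.frame(word_id = paste0("v", 1:9), phoneme = "b",
                     start_s = 0, end_s = 0.05)
  ph2 <- encode_phonemes(rbind(ann, filler, nine), min_count = 10)
  expect_false("b" %in% ph2$labels)
  # frames inside no retained interval are all -1
  M2 <- ph2$matrices[["v1"]]
  expect_true(all(M2 == -1))

  # column sums are -K or -K + 2 (at most one active phoneme per frame)
  two <- data.frame(word_id = "w2ph",
                    phoneme = rep(c("a", "b"), 6),
                    start_s = seq(0, 1.1, 0.1), end_s = seq(0.1, 1.2, 0.1))
  ph3 <- encode_phonemes(rbind(filler, nine, two, ann), min_count = 9)
  K <- length(ph3$labels)
  cs <- colSums(ph3$matrices[["w2ph"]])
  expect_true(all(cs %in% c(-K, -K + 2)))

  # overlapping intervals are rejected
  bad <- data.frame(word_id = "x", phoneme = c("a", "b"),
                    start_s = c(0, 0.05), end_s = c(0.1, 0.15))
  expect_error(encode_phonemes(rbind(filler, bad)), "overlapping")
})
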