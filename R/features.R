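#' Waveform container
#'
#' A validated mono waveform. All feature extractors expect audio resampled
#' to 16 kHz (resampling itself is assumed to have been done upstream).
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in samples/s (default 16000).
#' @return object of class `ct_waveform`.
#' @export
waveform <- function(samples, rate = 16000) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform is empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("waveform contains non-finite values", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("invalid sampling rate", call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "ct_waveform")
}

#' @export
print.ct_waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.0f ms)\n",
              length(x$samples), x$rate, 1000 * length(x$samples) / x$rate))
  invisible(x)
}

#' Auditory spectrogram
#'
#' Band x frame energy representation of a sound. The waveform is divided
#' into frames of `frame_step` seconds; each frame's power spectrum is
#' integrated over a Hann window of `integration_window` seconds starting at
#' the frame onset (frame t covers the half-open interval
#' `[t * frame_step, t * frame_step + integration_window)`, t = 0 at sound
#' onset) and pooled through the filterbank weights into band energies.
#'
#' @param w a [waveform()] (mono, 16 kHz).
#' @param filterbank an [auditory_filterbank()]; default 128 bands spanning
#'   180-7246 Hz.
#' @param frame_step frame hop in seconds (default 0.010).
#' @param integration_window integration window in seconds (default 0.016).
#' @return object of class `ct_spectrogram`: list with `values`
#'   (band x frame energy matrix), `center_freqs`, `frame_step`,
#'   `integration_window`. The frame count is `ceiling(duration / frame_step)`;
#'   trailing frames are zero-padded.
#' @examples
#' w <- waveform(sin(2 * pi * 1000 * seq(0, 0.5, by = 1/16000)))
#' s <- compute_spectrogram(w)
#' @export
compute_spectrogram <- function(w, filterbank = auditory_filterbank(),
                                frame_step = 0.010, integration_window = 0.016) {
  stopifnot(inherits(w, "ct_waveform"), inherits(filterbank, "ct_filterbank"))
  dur <- length(w$samples) / w$rate
  if (dur <= integration_window)
    stop("waveform shorter than the integration window", call. = FALSE)
  hop <- round(frame_step * w$rate)
  win_len <- round(integration_window * w$rate)
  n_frames <- as.integer(ceiling(length(w$samples) / hop))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))  # Hann
  # frame matrix (win_len x n_frames), zero-padded past the end of the sound
  idx <- outer(seq_len(win_len), (seq_len(n_frames) - 1L) * hop, `+`)
  x <- c(w$samples, numeric(max(0L, max(idx) - length(w$samples))))
  frames <- matrix(x[idx], nrow = win_len) * win
  P <- abs(stats::mvfft(frames))^2
  nb <- floor(win_len / 2) + 1L
  freqs <- (seq_len(nb) - 1L) * w$rate / win_len
  W <- filterbank$weights(freqs)
  values <- W %*% P[seq_len(nb), , drop = FALSE]
  structure(list(values = values, center_freqs = filterbank$center_freqs,
                 frame_step = frame_step, integration_window = integration_window),
            class = "ct_spectrogram")
}

#' @export
print.ct_spectrogram <- function(x, ...) {
  cat(sprintf("Auditory spectrogram: %d bands x %d frames (%.0f ms steps)\n",
              nrow(x$values), ncol(x$values), 1000 * x$frame_step))
  invisible(x)
}

#' Amplitude envelope
#'
#' The across-band mean of a spectrogram, one value per 10 ms frame. Tracks
#' syllable-rate energy fluctuations of the sound.
#'
#' @param s a `ct_spectrogram` (or a plain band x frame matrix).
#' @return object of class `ct_envelope`: list with `values` (one energy per
#'   frame) and `frame_step`.
#' @export
compute_envelope <- function(s) {
  if (inherits(s, "ct_spectrogram")) {
    v <- colMeans(s$values)
    fs <- s$frame_step
  } else if (is.matrix(s)) {
    v <- colMeans(s)
    fs <- 0.010
  } else stop("expected a ct_spectrogram or a band x frame matrix", call. = FALSE)
  structure(list(values = as.numeric(v), frame_step = fs), class = "ct_envelope")
}

#' Frequency spectrum through the auditory filterbank
#'
#' A non-time-varying representation of stimulus power per frequency band:
#' the full-sound periodogram pooled through the same 128-band filterbank
#' as the spectrogram.
#'
#' @inheritParams compute_spectrogram
#' @return object of class `ct_fft`: list with `values` (length `n_bands`,
#'   non-negative) and `center_freqs`.
#' @export
compute_fft_spectrum <- function(w, filterbank = auditory_filterbank()) {
  stopifnot(inherits(w, "ct_waveform"), inherits(filterbank, "ct_filterbank"))
  n <- length(w$samples)
  P <- abs(stats::fft(w$samples))^2 / n
  nb <- floor(n / 2) + 1L
  freqs <- (seq_len(nb) - 1L) * w$rate / n
  v <- as.numeric(filterbank$weights(freqs) %*% P[seq_len(nb)])
  structure(list(values = v, center_freqs = filterbank$center_freqs),
            class = "ct_fft")
}

#' Modulation power spectrum
#'
#' Energy of the joint spectral (cycles/octave) and temporal (Hz)
#' modulations of the log-spectrogram, measured with Gaussian
#' modulation-selective filters at four spectral scales and four temporal
#' rates. Upward- and downward-going modulations are not separated: filters
#' are symmetric in the sign of the modulation frequencies, so the two
#' directions are pooled into a single value per (scale, rate, band).
#'
#' @param s a `ct_spectrogram`.
#' @param scales spectral modulation centers, cycles/octave
#'   (default 0.5, 1, 2, 4).
#' @param rates temporal modulation centers, Hz (default 1, 3, 9, 27).
#' @return object of class `ct_mps`: `values` is a
#'   `length(scales) x length(rates) x n_bands` array of modulation
#'   energies; `scales` and `rates` are stored alongside.
#' @details If the spectrogram is shorter than the period of the slowest
#'   rate filter, it is zero-padded in time with a warning. Filters are
#'   Gaussian on the log2 modulation-frequency axis (sd = half the spacing
#'   between adjacent centers); the DC bin is assigned the lowest
#'   resolvable modulation frequency so that temporally constant input
#'   loads the slowest rate filter.
#' @export
compute_mps <- function(s, scales = c(0.5, 1, 2, 4), rates = c(1, 3, 9, 27)) {
  stopifnot(inherits(s, "ct_spectrogram"))
  V <- s$values
  nbnd <- nrow(V)
  if (ncol(V) < 2L) stop("spectrogram needs at least 2 frames", call. = FALSE)
  need <- ceiling(1 / (min(rates) * s$frame_step))
  if (ncol(V) < need) {
    warning(sprintf(paste0("spectrogram (%d frames) shorter than the slowest ",
                           "rate filter support (%d frames); zero-padding"),
                    ncol(V), need))
    V <- cbind(V, matrix(0, nbnd, need - ncol(V)))
  }
  nt <- ncol(V)
  L <- log(V + 1e-12)
  L <- L - mean(L)
  FT <- stats::fft(L)
  # modulation frequency axes
  oct_per_band <- log2(s$center_freqs[nbnd] / s$center_freqs[1L]) / (nbnd - 1L)
  f_s <- fft_freqs(nbnd) / oct_per_band          # cycles/octave
  f_t <- fft_freqs(nt) / s$frame_step            # Hz
  floor_s <- 1 / (nbnd * oct_per_band) / 2
  floor_t <- 1 / (nt * s$frame_step) / 2
  gs <- gauss_log_filter(abs(f_s), scales, floor_s)
  gt <- gauss_log_filter(abs(f_t), rates, floor_t)
  out <- array(0, dim = c(length(scales), length(rates), nbnd))
  for (i in seq_along(scales)) {
    for (j in seq_along(rates)) {
      G <- outer(gs[, i], gt[, j])
      filt <- Re(stats::fft(FT * G, inverse = TRUE)) / (nbnd * nt)
      out[i, j, ] <- rowMeans(filt^2)
    }
  }
  structure(list(values = out, scales = scales, rates = rates),
            class = "ct_mps")
}

# unshifted FFT bin frequencies in cycles/sample, signed
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Gaussian on the log2(|frequency|) axis, one column per center
gauss_log_filter <- function(absf, centers, dc_floor) {
  absf <- pmax(absf, dc_floor)
  lo <- log2(absf)
  sd <- if (length(centers) > 1L) mean(diff(log2(centers))) / 2 else 1
  vapply(centers, function(c0) exp(-(lo - log2(c0))^2 / (2 * sd^2)),
         numeric(length(absf)))
}

#' Encode a time-aligned phoneme annotation as a +/-1 sequence matrix
#'
#' Converts per-word phoneme interval tables into phoneme x frame matrices
#' at 10 ms resolution: +1 where the phoneme is present in the frame, -1
#' otherwise, with at most one active phoneme per frame. Only phonemes with
#' at least `min_count` instances across the whole stimulus set are retained
#' as rows.
#'
#' @param annotation data.frame with columns `word_id`, `phoneme`,
#'   `start_s`, `end_s` (times in seconds from word onset); intervals must
#'   not overlap within a word.
#' @param frame_step frame hop in seconds (default 0.010). A frame is
#'   active for a phoneme when its start time falls in
#'   `[start_s, end_s)`.
#' @param min_count minimum number of instances across the set for a
#'   phoneme to be retained (default 10).
#' @param n_frames optional named integer vector of frame counts per word;
#'   defaults to `ceiling(max(end_s) / frame_step)` per word.
#' @return object of class `ct_phonemes`: list with `matrices` (one
#'   phoneme x frame matrix of +/-1 per word), `labels` (retained phonemes)
#'   and `counts` (instances per phoneme, all phonemes).
#' @export
encode_phonemes <- function(annotation, frame_step = 0.010, min_count = 10,
                            n_frames = NULL) {
  req <- c("word_id", "phoneme", "start_s", "end_s")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns word_id, phoneme, start_s, end_s", call. = FALSE)
  if (any(annotation$end_s <= annotation$start_s))
    stop("invalid annotation: empty or negative intervals", call. = FALSE)
  counts <- table(annotation$phoneme)
  labels <- sort(names(counts)[counts >= min_count])
  words <- unique(annotation$word_id)
  eps <- 1e-9
  mats <- lapply(words, function(wid) {
    a <- annotation[annotation$word_id == wid, , drop = FALSE]
    a <- a[order(a$start_s), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start_s[-1L] < a$end_s[-nrow(a)] - eps))
      stop(sprintf("invalid annotation: overlapping intervals in word '%s'", wid),
           call. = FALSE)
    Tn <- if (!is.null(n_frames)) n_frames[[as.character(wid)]] else
      ceiling(max(a$end_s) / frame_step - eps)
    M <- matrix(-1, length(labels), Tn, dimnames = list(labels, NULL))
    ft <- (seq_len(Tn) - 1L) * frame_step
    for (r in seq_len(nrow(a))) {
      ph <- as.character(a$phoneme[r])
      if (!ph %in% labels) next
      on <- ft >= a$start_s[r] - eps & ft < a$end_s[r] - eps
      M[ph, on] <- 1
    }
    M
  })
  names(mats) <- as.character(words)
  structure(list(matrices = mats, labels = labels,
                 counts = as.integer(counts), phonemes = names(counts)),
            class = "ct_phonemes")
}

#' @export
print.ct_phonemes <- function(x, ...) {
  cat(sprintf("Phoneme sequences: %d words, %d retained phonemes (%s)\n",
              length(x$matrices), length(x$labels),
              paste(x$labels, collapse = " ")))
  invisible(x)
}
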