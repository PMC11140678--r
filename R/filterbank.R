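#' Log-spaced auditory filterbank
#'
#' Defines a bank of overlapping triangular band-pass weights with
#' geometrically spaced center frequencies, used by [compute_spectrogram()]
#' and [compute_fft_spectrum()] to pool short-time power spectra into
#' cochlea-like frequency bands. The object is a plain specification
#' (center frequencies plus a weight generator), so alternative filterbanks
#' can be plugged in anywhere one is accepted.
#'
#' @param n_bands number of frequency bands (default 128).
#' @param fmin,fmax lowest / highest band center frequency in Hz
#'   (defaults 180 and 7246).
#' @return An object of class `ct_filterbank` with elements
#'   `center_freqs` (Hz, strictly increasing) and `weights(freqs)`, a
#'   function returning an `n_bands x length(freqs)` non-negative weight
#'   matrix (triangular on the log-frequency axis, peak 1 at each center).
#' @examples
#' fb <- auditory_filterbank(16, 200, 4000)
#' w <- fb$weights(seq(100, 5000, by = 50))
#' @export
auditory_filterbank <- function(n_bands = 128L, fmin = 180, fmax = 7246) {
  stopifnot(n_bands >= 2L, fmin > 0, fmax > fmin)
  lc <- seq(log(fmin), log(fmax), length.out = n_bands)
  # extend one virtual center on each side so edge bands keep full triangles
  step <- lc[2L] - lc[1L]
  lo <- c(lc[1L] - step, lc[-n_bands])
  hi <- c(lc[-1L], lc[n_bands] + step)
  weights <- function(freqs) {
    lf <- suppressWarnings(log(freqs))
    lf[!is.finite(lf)] <- -Inf  # DC / non-positive frequencies get zero weight
    W <- matrix(0, n_bands, length(freqs))
    for (k in seq_len(n_bands)) {
      up <- (lf - lo[k]) / (lc[k] - lo[k])
      dn <- (hi[k] - lf) / (hi[k] - lc[k])
      W[k, ] <- pmax(0, pmin(up, dn))
    }
    W
  }
  structure(list(n_bands = as.integer(n_bands), fmin = fmin, fmax = fmax,
                 center_freqs = exp(lc), weights = weights),
            class = "ct_filterbank")
}

#' @export
print.ct_filterbank <- function(x, ...) {
  cat(sprintf("Auditory filterbank: %d log-spaced bands, %.0f-%.0f Hz\n",
              x$n_bands, x$fmin, x$fmax))
  invisible(x)
}
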