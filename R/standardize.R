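#' Standardize a feature set across stimuli
#'
#' Z-scores stimulus features across the stimulus set so that every feature
#' has mean 0 and standard deviation 1 over the set. The grouping follows
#' the decoding convention: band x time features (spectrograms) are pooled
#' within each frequency band across all stimuli and frames; static vectors
#' per stimulus (frequency spectra, semantic vectors) within each feature
#' column; modulation spectra within each (scale, rate, band) cell; and
#' scalar-per-frame features (envelopes) across all stimuli and frames.
#' The population standard deviation (divide by n) is used throughout, so a
#' two-stimulus feature with values {1, 3} standardizes exactly to {-1, +1}.
#'
#' @param x one of: a list of band x frame matrices (one per stimulus,
#'   equal band count); a list of numeric vectors of per-frame values; a
#'   list of equal-dimension arrays; or a stimuli x features matrix.
#' @param state optional standardization state from a previous call; when
#'   supplied, its means/sds are applied instead of being re-estimated.
#' @return list with `x` (standardized, same shape as input) and `state`
#'   (class `ct_scaler`: `mean`, `sd`, `kind`). Zero-variance features are
#'   centered at 0 with `sd` recorded as 0 (with a warning) and are restored
#'   exactly by [unstandardize_features()].
#' @export
standardize_features <- function(x, state = NULL) {
  if (is.matrix(x)) {
    kind <- "columns"
    flat <- x
  } else if (is.list(x) && is.matrix(x[[1L]])) {
    kind <- "band"
    flat <- do.call(cbind, x)               # bands x (all frames)
  } else if (is.list(x) && is.array(x[[1L]])) {
    kind <- "cell"
    flat <- t(vapply(x, as.numeric, numeric(length(x[[1L]]))))
  } else if (is.list(x)) {
    kind <- "pooled"
    flat <- matrix(unlist(lapply(x, as.numeric)), ncol = 1L)
  } else stop("unsupported feature container", call. = FALSE)
  if (is.null(state)) {
    if ((if (kind == "band") ncol(flat) else nrow(flat)) < 2L)
      stop("need at least 2 stimuli/observations to standardize", call. = FALSE)
    if (kind == "band") {
      m <- rowMeans(flat); s <- sqrt(rowMeans((flat - m)^2))
    } else {
      m <- colMeans(flat); s <- sqrt(colMeans(sweep(flat, 2L, m)^2))
    }
    if (any(s == 0)) {
      warning("zero-variance feature(s): left centered at 0, sd recorded as 0")
    }
    state <- structure(list(mean = m, sd = s, kind = kind), class = "ct_scaler")
  } else {
    stopifnot(inherits(state, "ct_scaler"), identical(state$kind, kind))
  }
  div <- ifelse(state$sd == 0, 1, state$sd)
  out <- switch(kind,
    columns = sweep(sweep(x, 2L, state$mean), 2L, div, `/`),
    band = lapply(x, function(M) (M - state$mean) / div),
    cell = lapply(x, function(A) array((as.numeric(A) - state$mean) / div,
                                       dim = dim(A))),
    pooled = lapply(x, function(v) (as.numeric(v) - state$mean) / div))
  list(x = out, state = state)
}

#' Invert a standardization
#'
#' @param x standardized features in the same shape accepted by
#'   [standardize_features()].
#' @param state the `ct_scaler` returned with them.
#' @return features on the original scale.
#' @export
unstandardize_features <- function(x, state) {
  stopifnot(inherits(state, "ct_scaler"))
  mul <- ifelse(state$sd == 0, 1, state$sd)
  switch(state$kind,
    columns = sweep(sweep(x, 2L, mul, `*`), 2L, state$mean, `+`),
    band = lapply(x, function(M) M * mul + state$mean),
    cell = lapply(x, function(A) array(as.numeric(A) * mul + state$mean,
                                       dim = dim(A))),
    pooled = lapply(x, function(v) v * mul + state$mean))
}

#' Standardize evoked responses across stimuli
#'
#' Normalizes the sensor signal within each (sensor, 10 ms time window)
#' cell to mean 0 and population standard deviation 1 across the stimulus
#' set, the response-side counterpart of [standardize_features()].
#'
#' @param r a stimulus x sensor x time numeric array (or an `ct_evoked`
#'   object, whose array is standardized in place).
#' @param state optional `ct_scaler` to apply instead of re-estimating.
#' @return list with `x` (same shape) and `state`.
#' @export
standardize_responses <- function(r, state = NULL) {
  obj <- NULL
  if (inherits(r, "ct_evoked")) { obj <- r; r <- r$data }
  stopifnot(is.array(r), length(dim(r)) == 3L)
  n <- dim(r)[1L]
  flat <- matrix(r, nrow = n)               # stimuli x (sensor*time)
  res <- standardize_features(flat, state)
  out <- array(res$x, dim = dim(r), dimnames = dimnames(r))
  if (!is.null(obj)) { obj$data <- out; out <- obj }
  list(x = out, state = res$state)
}
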