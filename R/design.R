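#' Evoked response container
#'
#' Holds a set of trial-averaged sensor responses, one epoch per stimulus,
#' on a common time axis.
#'
#' @param data stimulus x sensor x time numeric array.
#' @param rate sampling rate in Hz (default 100).
#' @param onset index of the first post-onset sample (time 0); samples
#'   before it are the pre-stimulus baseline.
#' @param ids stimulus identifiers (default `S1..Sn`).
#' @param lengths per-stimulus feature lengths in frames (stimulus
#'   durations); default: everything after onset.
#' @return object of class `ct_evoked`.
#' @export
evoked_set <- function(data, rate = 100, onset = 1L, ids = NULL, lengths = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (length(ids) != n) stop("stimulus id count does not match array", call. = FALSE)
  if (onset < 1L || onset > dim(data)[3L])
    stop("onset index beyond array bounds", call. = FALSE)
  if (is.null(lengths)) lengths <- rep(dim(data)[3L] - onset + 1L, n)
  if (length(lengths) != n || any(lengths < 1L))
    stop("invalid per-stimulus lengths", call. = FALSE)
  structure(list(data = data, rate = rate, onset = as.integer(onset),
                 ids = as.character(ids), lengths = as.integer(lengths)),
            class = "ct_evoked")
}

#' @export
print.ct_evoked <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Evoked responses: %d stimuli x %d sensors x %d samples @ %g Hz (onset at %d)\n",
              d[1L], d[2L], d[3L], x$rate, x$onset))
  invisible(x)
}

#' Lagged design matrices for the convolution decoder
#'
#' For every stimulus and every feature frame t, assembles the row of
#' response samples delayed by tau, `r(t + tau, x)`, for lags tau from
#' `lag_ms[1]` to `lag_ms[2]` over all sensors. Lags are positive delays
#' from stimulus to response: the neural activation follows each stimulus
#' time point, so frame t is decoded from response samples recorded tau
#' later. Columns are ordered lag-major (all sensors at the first lag,
#' then all sensors at the next lag, ...). Samples falling outside the
#' epoch are zero-filled.
#'
#' @param evoked a [evoked_set()] (or plain 3-D array at 100 Hz, onset 1).
#' @param lag_ms two-element numeric, lag window start/end in ms
#'   (`lag_ms[1] <= lag_ms[2]`, both >= 0). A 20-420 ms window at 100 Hz
#'   gives 41 lag samples per sensor.
#' @param lengths number of rows (feature frames) per stimulus; defaults to
#'   the evoked set's stimulus lengths.
#' @return object of class `ct_lagged`: list with `blocks` (one
#'   `T_n x (n_lags * n_sensors)` matrix per stimulus), `lags` (samples),
#'   `lag_ms`, `n_sensors`, `lengths`, `ids`.
#' @export
lagged_design <- function(evoked, lag_ms = c(20, 420), lengths = NULL) {
  if (!inherits(evoked, "ct_evoked")) evoked <- evoked_set(evoked)
  if (lag_ms[1L] > lag_ms[2L]) stop("lag window start exceeds end", call. = FALSE)
  if (lag_ms[1L] < 0) stop("lags must be non-negative delays", call. = FALSE)
  l1 <- as.integer(round(lag_ms[1L] * evoked$rate / 1000))
  l2 <- as.integer(round(lag_ms[2L] * evoked$rate / 1000))
  lags <- l1:l2
  if (is.null(lengths)) lengths <- evoked$lengths
  ns <- dim(evoked$data)[2L]
  nt <- dim(evoked$data)[3L]
  blocks <- lapply(seq_along(lengths), function(n) {
    Tn <- lengths[n]
    R <- evoked$data[n, , , drop = TRUE]
    if (is.null(dim(R))) R <- matrix(R, nrow = 1L)  # single sensor
    X <- matrix(0, Tn, length(lags) * ns)
    for (j in seq_along(lags)) {
      # sample index for frame t at delay l: onset + (t - 1) + l
      src <- evoked$onset + (seq_len(Tn) - 1L) + lags[j]
      ok <- src >= 1L & src <= nt
      cols <- ((j - 1L) * ns + 1L):(j * ns)
      X[ok, cols] <- t(R[, src[ok], drop = FALSE])
    }
    X
  })
  structure(list(blocks = blocks, lags = lags, lag_ms = lag_ms,
                 n_sensors = ns, lengths = as.integer(lengths),
                 ids = evoked$ids),
            class = "ct_lagged")
}

#' @export
print.ct_lagged <- function(x, ...) {
  cat(sprintf("Lagged design: %d stimuli, %d lags (%g-%g ms) x %d sensors = %d columns\n",
              length(x$blocks), length(x$lags), x$lag_ms[1L], x$lag_ms[2L],
              x$n_sensors, length(x$lags) * x$n_sensors))
  invisible(x)
}
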