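# File formats: minimal RIFF/PCM WAV audio, a TSV + JSON plain-text
# container for evoked arrays, and YAML/JSON run configuration.

#' Read a mono PCM WAV file
#'
#' Minimal RIFF reader for uncompressed PCM audio (8/16/32-bit integer),
#' returning amplitudes scaled to [-1, 1]. Multichannel files are refused:
#' stimuli are expected as mono 16 kHz audio.
#'
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      bytes <- fmt$bits / 8L
      n <- sz %/% bytes
      samples <- switch(as.character(fmt$bits),
        "8" = (readBin(con, "integer", n, 1L, signed = FALSE) - 128) / 128,
        "16" = readBin(con, "integer", n, 2L, signed = TRUE,
                       endian = "little") / 32768,
        "32" = readBin(con, "integer", n, 4L, endian = "little") / 2147483648,
        stop("unsupported bit depth", call. = FALSE))
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  if (fmt$audio_format != 1L) stop("only PCM WAV is supported", call. = FALSE)
  if (fmt$channels != 1L) stop("expected mono audio", call. = FALSE)
  waveform(samples, rate = fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param w a [waveform()]; amplitudes are clipped to [-1, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "ct_waveform"))
  x <- as.integer(round(pmax(-1, pmin(1, w$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")       # PCM, mono
  writeBin(as.integer(w$rate), con, 4L, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")      # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4L, endian = "little")
  writeBin(x, con, 2L, endian = "little")
  invisible(path)
}

#' Write / read an evoked-response set as TSV + JSON
#'
#' Serializes a [evoked_set()] to a directory holding `meta.json`
#' (dimensions, rate, onset, ids, per-stimulus lengths) and `data.tsv`
#' (one row per stimulus x sensor, one column per time sample): a
#' language-neutral plain-text container.
#'
#' @param evoked a [evoked_set()].
#' @param dir output directory (created if missing).
#' @return `dir` (write) or a validated [evoked_set()] (read).
#' @export
write_evoked <- function(evoked, dir) {
  stopifnot(inherits(evoked, "ct_evoked"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(evoked$data)
  meta <- list(n_stimuli = d[1L], n_sensors = d[2L], n_time = d[3L],
               rate = evoked$rate, onset = evoked$onset, ids = evoked$ids,
               lengths = evoked$lengths)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(aperm(evoked$data, c(3L, 2L, 1L)), ncol = d[3L],
                 byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_evoked
#' @export
read_evoked <- function(dir) {
  mpath <- file.path(dir, "meta.json")
  dpath <- file.path(dir, "data.tsv")
  if (!file.exists(mpath) || !file.exists(dpath))
    stop("evoked container is missing meta.json or data.tsv", call. = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  need <- c("n_stimuli", "n_sensors", "n_time", "rate", "onset", "ids",
            "lengths")
  if (!all(need %in% names(meta)))
    stop("evoked container metadata is incomplete", call. = FALSE)
  flat <- as.matrix(utils::read.table(dpath, sep = "\t"))
  if (nrow(flat) != meta$n_stimuli * meta$n_sensors ||
      ncol(flat) != meta$n_time)
    stop("evoked data shape does not match metadata", call. = FALSE)
  if (length(meta$ids) != meta$n_stimuli)
    stop("stimulus id count does not match array", call. = FALSE)
  arr <- aperm(array(t(flat), dim = c(meta$n_time, meta$n_sensors,
                                      meta$n_stimuli)), c(3L, 2L, 1L))
  evoked_set(arr, rate = meta$rate, onset = meta$onset, ids = meta$ids,
             lengths = meta$lengths)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("invalid config: ", conditionMessage(e),
                                      call. = FALSE))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop("invalid config: ", conditionMessage(e),
                                      call. = FALSE))
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.list(cfg)) stop("invalid config: expected a mapping", call. = FALSE)
  cfg
}

# cohort_spec from a config list (missing fields fall back to defaults)
spec_from_config <- function(cfg, seed = NULL) {
  cs <- cfg$cohort
  if (is.null(cs)) cs <- list()
  args <- cs[names(cs) %in% names(formals(cohort_spec))]
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(cohort_spec, args)
}

#' Write long-format feature tables
#'
#' Envelope values as a three-column TSV (`stimulus`, `frame`, `value`);
#' used by the command-line pipeline and readable by any tool.
#'
#' @param envelopes list of per-frame numeric vectors.
#' @param ids stimulus identifiers.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_envelopes_tsv <- function(envelopes, ids, path) {
  df <- do.call(rbind, lapply(seq_along(envelopes), function(i)
    data.frame(stimulus = ids[i], frame = seq_along(envelopes[[i]]),
               value = as.numeric(envelopes[[i]]))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_envelopes_tsv <- function(path) {
  df <- utils::read.delim(path)
  ids <- unique(df$stimulus)
  envs <- lapply(ids, function(s) df$value[df$stimulus == s])
  names(envs) <- ids
  envs
}
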