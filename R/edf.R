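# Minimal European Data Format (EDF) I/O.
#
# EDF stores a fixed-layout ASCII header (256 bytes, plus 256 per signal)
# followed by data records of 16-bit little-endian integers, mapped to
# physical units by a per-signal linear calibration. Only the features the
# package needs are supported: continuous recordings, 1 s data records, an
# integer number of samples per record per signal.

edf_int16_min <- -32768L
edf_int16_max <- 32767L

read_edf_header <- function(con) {
  field <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n) {
      abort("EDF header truncated.", class = "hflf_error_bad_edf")
    }
    trimws(raw)
  }
  h <- list(
    version = field(8), patient = field(80), recording = field(80),
    startdate = field(8), starttime = field(8),
    header_bytes = suppressWarnings(as.integer(field(8))),
    reserved = field(44),
    n_records = suppressWarnings(as.integer(field(8))),
    record_duration = suppressWarnings(as.numeric(field(8))),
    n_signals = suppressWarnings(as.integer(field(4)))
  )
  if (is.na(h$n_signals) || h$n_signals < 1L ||
      is.na(h$n_records) || is.na(h$record_duration) ||
      h$record_duration <= 0) {
    abort("Not a readable EDF file: malformed global header.",
          class = "hflf_error_bad_edf")
  }
  ns <- h$n_signals
  sig_field <- function(n) vapply(seq_len(ns), function(i) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n) {
      abort("EDF signal header truncated.", class = "hflf_error_bad_edf")
    }
    trimws(raw)
  }, character(1))
  h$label <- sig_field(16)
  h$transducer <- sig_field(80)
  h$phys_dim <- sig_field(8)
  h$phys_min <- as.numeric(sig_field(8))
  h$phys_max <- as.numeric(sig_field(8))
  h$dig_min <- as.integer(sig_field(8))
  h$dig_max <- as.integer(sig_field(8))
  h$prefilter <- sig_field(80)
  h$spr <- as.integer(sig_field(8))
  h$sig_reserved <- sig_field(32)
  if (anyNA(h$spr) || any(h$spr < 1L) || anyNA(h$phys_min) ||
      anyNA(h$phys_max) || anyNA(h$dig_min) || anyNA(h$dig_max) ||
      any(h$dig_max <= h$dig_min)) {
    abort("Not a readable EDF file: malformed signal headers.",
          class = "hflf_error_bad_edf")
  }
  h
}

#' List the signal channels of an EDF file
#'
#' @param path Path to an EDF file.
#' @return A tibble with one row per signal: `label`, `sampling_rate_hz`,
#'   `physical_dim`, `n_samples`.
#' @export
read_edf_channels <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("EDF file not found: ", path),
          class = "hflf_error_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  tibble::tibble(
    label = h$label,
    sampling_rate_hz = h$spr / h$record_duration,
    physical_dim = h$phys_dim,
    n_samples = h$spr * h$n_records
  )
}

#' Read one EMG channel from an EDF file
#'
#' Reads the named signal from a European Data Format file and applies the
#' header's linear calibration to return physical-unit (microvolt) samples.
#'
#' @param path Path to an EDF file.
#' @param channel Signal label to extract (matched after trimming
#'   whitespace).
#' @return An [emg_recording()] with the channel's samples and the sampling
#'   rate implied by the header (samples per record / record duration).
#' @export
read_emg_edf <- function(path, channel) {
  if (!file.exists(path)) {
    abort(paste0("EDF file not found: ", path),
          class = "hflf_error_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  k <- match(trimws(channel), h$label)
  if (is.na(k)) {
    abort(
      paste0("Channel '", channel, "' not found in EDF; available: ",
             paste(h$label, collapse = ", ")),
      class = "hflf_error_channel_not_found"
    )
  }
  rec_len <- sum(h$spr)
  vals <- readBin(con, "integer", n = rec_len * h$n_records, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) < rec_len * h$n_records) {
    abort("EDF data section shorter than header declares.",
          class = "hflf_error_bad_edf")
  }
  offsets <- c(0L, cumsum(h$spr))
  dig <- matrix(vals, nrow = rec_len)[(offsets[k] + 1L):offsets[k + 1L], ,
                                      drop = FALSE]
  gain <- (h$phys_max[k] - h$phys_min[k]) / (h$dig_max[k] - h$dig_min[k])
  phys <- (as.vector(dig) - h$dig_min[k]) * gain + h$phys_min[k]
  emg_recording(phys, h$spr[k] / h$record_duration,
                channel_label = h$label[k])
}

fmt_edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  if (nchar(s) > width) {
    abort("Cannot format value into an 8-byte EDF field.",
          class = "hflf_error_bad_edf")
  }
  s
}

pad_field <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Write recordings to an EDF file
#'
#' Writes one or more [emg_recording()] channels as a continuous EDF file
#' with 1 s data records. Sampling rates must be whole numbers per second.
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' just covering the data, so a write/read round trip reproduces the signal
#' to quantization tolerance (physical range / 65535). Channels shorter than
#' the longest one are zero-padded to a whole number of records.
#'
#' @param recordings An [emg_recording()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1), "emg_recording")))
  ns <- length(recordings)
  spr <- vapply(recordings, function(r) r$sampling_rate, double(1))
  if (any(abs(spr - round(spr)) > 1e-9)) {
    abort("EDF writer requires integer samples-per-second.",
          class = "hflf_error_bad_edf")
  }
  spr <- as.integer(round(spr))
  n_records <- max(ceiling(vapply(recordings, function(r)
    length(r$samples), double(1)) / spr))

  phys_hi <- vapply(recordings, function(r) {
    m <- max(abs(r$samples), na.rm = TRUE)
    max(1, ceiling(m))
  }, double(1))
  phys_lo <- -phys_hi

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(pad_field(s, width), con, eos = NULL)

  wr("0", 8); wr("X X X X", 80); wr("Startdate 01.01.2000 X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8); wr("", 44)
  wr(as.character(n_records), 8); wr("1", 8); wr(as.character(ns), 4)

  for (r in recordings) wr(r$channel_label, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(fmt_edf_num(phys_lo[i]), 8)
  for (i in seq_len(ns)) wr(fmt_edf_num(phys_hi[i]), 8)
  for (i in seq_len(ns)) wr(as.character(edf_int16_min), 8)
  for (i in seq_len(ns)) wr(as.character(edf_int16_max), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr[i]), 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- recordings[[i]]$samples
    x <- c(x, double(n_records * spr[i] - length(x)))
    scale <- (edf_int16_max - edf_int16_min) / (phys_hi[i] - phys_lo[i])
    d <- as.integer(round((x - phys_lo[i]) * scale)) + edf_int16_min
    dig[[i]] <- matrix(pmin(pmax(d, edf_int16_min), edf_int16_max),
                       nrow = spr[i])
  }
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][, rec], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
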