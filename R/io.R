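# Recording input/output: a plain CSV dialect (one header row of channel
# names, one column per channel, amplitudes in microvolts, sampling rate and
# annotation in a JSON sidecar <path>.json) and a minimal EDF (European Data
# Format) reader/writer for continuous signals. EDF annotations live in a
# two-column sidecar text file (patient_id, pges_end_seconds) because the
# source annotations are single expert-marked timestamps, not an EDF+
# annotation stream.

sidecar_path <- function(path) paste0(path, ".json")

#' Read an EEG recording from disk
#'
#' @param path Path to a `.csv` or `.edf` file written by
#'   [write_recording()] (or any EDF file with continuous equal-rate
#'   signals).
#' @param format `"csv"` or `"edf"`; guessed from the file extension by
#'   default.
#' @return A [recording()]; the end-of-PGES annotation is populated when the
#'   sidecar file is present.
#' @export
read_recording <- function(path, format = c("guess", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
}

#' Write an EEG recording to disk
#'
#' CSV keeps full floating-point precision; EDF quantizes each channel to
#' 16-bit integers over a shared symmetric physical range, so round-trip
#' error is bounded by half the quantization step (physical range / 2^16).
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("guess", "csv", "edf")) {
  stopifnot(inherits(rec, "pges_recording"))
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") write_recording_csv(rec, path)
  else write_recording_edf(rec, path)
  invisible(path)
}

read_recording_csv <- function(path) {
  dat <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE, fill = TRUE),
    error = function(e) stop_format(sprintf("cannot parse CSV '%s': %s",
                                            path, conditionMessage(e))))
  if (ncol(dat) < 1 || is.null(names(dat)) || any(names(dat) == "")) {
    stop_schema(sprintf("CSV '%s' has no channel labels", path))
  }
  if (anyNA(dat)) {
    stop_schema(sprintf("CSV '%s' has channels of unequal length", path))
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop_schema(sprintf("sidecar metadata '%s' is missing", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop_schema("sidecar metadata lacks 'fs'")
  recording(as.matrix(dat), fs = meta$fs, channel_names = names(dat),
            patient_id = if (is.null(meta$patient_id)) "unknown"
                         else meta$patient_id,
            pges_end_s = meta$pges_end_s)
}

write_recording_csv <- function(rec, path) {
  data.table::fwrite(as.data.frame(rec$samples), path)
  meta <- list(fs = rec$fs, patient_id = rec$patient_id)
  if (!is.null(rec$pges_end_s)) meta$pges_end_s <- rec$pges_end_s
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

# --- EDF ---------------------------------------------------------------

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

write_recording_edf <- function(rec, path) {
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  # one data record holding the whole signal keeps arbitrary durations exact
  phys_max <- max(1, ceiling(max(abs(rec$samples))))
  dig_max <- 32767L
  scaled <- round(rec$samples / phys_max * dig_max)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(sprintf("cannot open '%s'", path)))
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(substr(rec$patient_id, 1, 80), 80),
    edf_pad("synthetic EEG", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8),
    edf_pad("", 44),
    edf_pad(1, 8),                        # number of data records
    edf_pad(format(n / rec$fs, digits = 8), 8),
    edf_pad(ns, 4))
  sig <- paste0(
    paste(edf_pad(substr(rec$channel_names, 1, 16), 16), collapse = ""),
    paste(rep(edf_pad("EEG", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(-phys_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (j in seq_len(ns)) {
    writeBin(as.integer(scaled[, j]), con, size = 2, endian = "little")
  }
  meta <- list(fs = rec$fs, patient_id = rec$patient_id)
  if (!is.null(rec$pges_end_s)) meta$pges_end_s <- rec$pges_end_s
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_recording_edf <- function(path) {
  con <- tryCatch(file(path, "rb"),
                  error = function(e) stop_io(sprintf("cannot open '%s'", path)))
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop_format("EDF header truncated")
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  patient <- fld(9, 80)
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  ns <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop_format("EDF header fields unparseable")
  }
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig, type = "bytes") < 256 * ns) stop_format("EDF header truncated")
  sfld <- function(block_start, len, j) {
    trimws(substr(sig, block_start + (j - 1) * len + 1,
                  block_start + j * len))
  }
  labels <- vapply(seq_len(ns), function(j) sfld(0, 16, j), character(1))
  off <- 16 * ns + 80 * ns + 8 * ns
  phys_min <- as.numeric(vapply(seq_len(ns),
                                function(j) sfld(off, 8, j), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns),
                                function(j) sfld(off + 8 * ns, 8, j),
                                character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns),
                               function(j) sfld(off + 16 * ns, 8, j),
                               character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns),
                               function(j) sfld(off + 24 * ns, 8, j),
                               character(1)))
  spr <- as.integer(vapply(seq_len(ns),
                           function(j) sfld(off + 32 * ns + 80 * ns, 8, j),
                           character(1)))
  if (length(unique(spr)) != 1) {
    stop_format("EDF signals with differing sample rates are not supported")
  }
  fs <- spr[1] / rec_dur
  samples <- matrix(0, nrow = spr[1] * n_rec, ncol = ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[j], size = 2, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[j]) stop_format("EDF data records truncated")
      gain <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
      samples[(r - 1) * spr[1] + seq_len(spr[j]), j] <-
        phys_min[j] + gain * (raw - dig_min[j])
    }
  }
  colnames(samples) <- labels
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else list()
  recording(samples, fs = fs, channel_names = labels,
            patient_id = if (!is.null(meta$patient_id)) meta$patient_id
                         else patient,
            pges_end_s = meta$pges_end_s)
}

#' Read a two-column annotation sidecar table
#'
#' Parses whitespace- or comma-separated lines of `patient_id,
#' pges_end_seconds`, the plain-text exchange format for expert end-of-PGES
#' annotations.
#'
#' @param path Path to the annotation file.
#' @return A data frame with columns `patient_id` and `pges_end_s`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- gsub(",", " ", readLines(path))
  utils::read.table(text = lines, header = FALSE, sep = "",
                    col.names = c("patient_id", "pges_end_s"),
                    colClasses = c("character", "numeric"))
}
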