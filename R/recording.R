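#' Multi-channel EEG recording
#'
#' Canonical container for a scalp EEG recording: a samples matrix (one
#' column per channel, amplitudes in microvolts), a sampling rate, and an
#' optional annotation giving the end of postictal generalized EEG
#' suppression (PGES) in seconds from recording start. Recordings without a
#' PGES episode carry `pges_end_s = NULL`.
#'
#' @param samples Numeric matrix, one column per channel, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of unique channel labels; defaults
#'   to the column names of `samples`.
#' @param patient_id Opaque patient identifier.
#' @param pges_end_s Optional end-of-PGES annotation in seconds (fractional
#'   allowed), or `NULL` when the recording has none.
#' @return An object of class `pges_recording`.
#' @export
recording <- function(samples, fs, channel_names = colnames(samples),
                      patient_id = "unknown", pges_end_s = NULL) {
  samples <- as.matrix(samples)
  if (!is_number(fs) || fs <= 0) stop_argument("fs must be a positive number")
  if (is.null(channel_names) || length(channel_names) != ncol(samples)) {
    stop_schema("channel labels missing or not one per channel")
  }
  if (anyDuplicated(channel_names)) {
    stop_schema("channel names must be unique")
  }
  dur <- nrow(samples) / fs
  if (!is.null(pges_end_s)) {
    if (!is_number(pges_end_s) || pges_end_s < 0 || pges_end_s > dur) {
      stop_argument(sprintf(
        "pges_end_s must lie in [0, %g] (recording duration)", dur))
    }
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         patient_id = patient_id, pges_end_s = pges_end_s),
    class = "pges_recording")
}

#' @export
print.pges_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %.2f s at %g Hz\n",
              x$patient_id, ncol(x$samples), nrow(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (is.null(x$pges_end_s)) cat("  no end-of-PGES annotation\n")
  else cat(sprintf("  end of PGES at %.3f s\n", x$pges_end_s))
  invisible(x)
}

recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Bipolar montage definition
#'
#' A longitudinal bipolar montage: each derived channel is the samplewise
#' difference between an anode and a cathode electrode. The default is the
#' 10-channel double-banana layout FP1-F7, F7-T7, T7-P7, P7-O1, FP2-F8,
#' F8-T8, T8-P8, P8-O2, Fz-Cz, Cz-Pz; derived channels are referred to by
#' the name of their first electrode, giving the canonical channel order
#' FP1, F7, T7, P7, FP2, F8, T8, P8, Fz, Cz used by every downstream
#' feature index.
#'
#' @param anodes Character vector of anode electrode labels.
#' @param cathodes Character vector of cathode electrode labels, same length.
#' @return An object of class `pges_montage` with elements `anodes`,
#'   `cathodes` and `short_names`.
#' @export
bipolar_montage <- function(
    anodes = c("FP1", "F7", "T7", "P7", "FP2", "F8", "T8", "P8", "Fz", "Cz"),
    cathodes = c("F7", "T7", "P7", "O1", "F8", "T8", "P8", "O2", "Cz", "Pz")) {
  if (length(anodes) != length(cathodes) || length(anodes) < 1) {
    stop_argument("anodes and cathodes must be non-empty and equal length")
  }
  structure(list(anodes = anodes, cathodes = cathodes, short_names = anodes),
            class = "pges_montage")
}

#' Canonical 10-channel order
#'
#' @return The channel short names FP1, F7, T7, P7, FP2, F8, T8, P8, Fz, Cz
#'   in the fixed order used throughout the package.
#' @export
canonical_channels <- function() bipolar_montage()$short_names

#' Apply a bipolar montage to an electrode-referential recording
#'
#' Derives each montage channel as anode minus cathode, samplewise, and
#' names it by its first electrode. Electrode lookup is case-insensitive
#' (recordings label the frontal-polar electrodes variously FP1/Fp1).
#'
#' @param rec A [recording()] whose channels are electrode signals.
#' @param montage A [bipolar_montage()].
#' @return A `pges_recording` with one channel per derivation, annotation
#'   carried over.
#' @export
apply_montage <- function(rec, montage = bipolar_montage()) {
  stopifnot(inherits(rec, "pges_recording"), inherits(montage, "pges_montage"))
  lookup <- function(el) {
    i <- match(toupper(el), toupper(rec$channel_names))
    if (is.na(i)) stop_montage(sprintf(
      "electrode '%s' required by the montage is absent from the recording", el))
    i
  }
  ia <- vapply(montage$anodes, lookup, integer(1))
  ic <- vapply(montage$cathodes, lookup, integer(1))
  out <- rec$samples[, ia, drop = FALSE] - rec$samples[, ic, drop = FALSE]
  colnames(out) <- montage$short_names
  recording(out, rec$fs, montage$short_names, rec$patient_id, rec$pges_end_s)
}

# Fourier-domain resampling of one series from n to m points (the FFT
# truncation/zero-padding method, with the usual Nyquist-bin bookkeeping).
fourier_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  k <- min(m, n)
  nyq <- k %/% 2L + 1L                       # bins 1..nyq: DC + positive freqs
  Y <- complex(m)
  Y[seq_len(nyq)] <- X[seq_len(nyq)]
  if (k > nyq) {                              # negative-frequency bins
    idx <- seq_len(k - nyq)
    Y[m - (k - nyq) + idx] <- X[n - (k - nyq) + idx]
  }
  if (k %% 2L == 0L) {
    h <- k %/% 2L
    if (m < n) {                              # fold the split Nyquist bin
      Y[h + 1L] <- Y[h + 1L] + X[n - h + 1L]
    } else {                                  # split the Nyquist bin in two
      Y[h + 1L] <- Y[h + 1L] / 2
      Y[m - h + 1L] <- Y[h + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording to a target rate
#'
#' Frequency-domain (FFT) resampling of every channel; content below the
#' Nyquist frequency of both rates is preserved. The annotation, expressed
#' in seconds, is unchanged. A recording already at the target rate is
#' returned as-is.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz (default 200, the canonical
#'   rate of the pipeline).
#' @return The resampled `pges_recording`.
#' @export
resample_to <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "pges_recording"))
  if (!is_number(target_fs) || target_fs <= 0) {
    stop_argument("target_fs must be a positive number")
  }
  if (target_fs == rec$fs) return(rec)
  n_in <- nrow(rec$samples)
  m <- as.integer(round(n_in * target_fs / rec$fs))
  out <- apply(rec$samples, 2, fourier_resample, m = m)
  colnames(out) <- rec$channel_names
  pg <- rec$pges_end_s
  if (!is.null(pg)) pg <- min(pg, m / target_fs)  # rounding can shave < 1 sample
  recording(out, target_fs, rec$channel_names, rec$patient_id, pg)
}
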