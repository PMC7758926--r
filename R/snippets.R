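#' Fixed-length EEG snippet
#'
#' The unit of classification: a 10-s, 10-channel window cut from a montaged
#' recording, labeled positive when it contains the annotated end of PGES.
#'
#' @param samples Numeric matrix (samples x channels) in microvolts; at
#'   200 Hz a 10-s snippet has 2000 rows.
#' @param fs Sampling rate in Hz.
#' @param label 0/1; 1 when the window contains the end of PGES.
#' @param patient_id Source patient identifier.
#' @param start_s Window start offset in the source recording, seconds.
#' @return An object of class `pges_snippet`.
#' @export
snippet <- function(samples, fs = 200, label = 0L, patient_id = "unknown",
                    start_s = 0) {
  samples <- as.matrix(samples)
  if (!is_number(fs) || fs <= 0) stop_argument("fs must be positive")
  if (!label %in% c(0L, 1L)) stop_argument("label must be 0 or 1")
  structure(
    list(samples = samples, fs = fs, label = as.integer(label),
         patient_id = patient_id, start_s = start_s),
    class = "pges_snippet")
}

#' @export
print.pges_snippet <- function(x, ...) {
  cat(sprintf(
    "EEG snippet '%s' @ %.2f s: %d channels x %.1f s at %g Hz, label %d\n",
    x$patient_id, x$start_s, ncol(x$samples), nrow(x$samples) / x$fs,
    x$fs, x$label))
  invisible(x)
}

snippet_duration_s <- 10

#' Cut labeled 10-s snippets from an annotated recording
#'
#' Windows of 10 s are placed at uniformly random start times on the sample
#' grid. A window is positive exactly when the annotated end of PGES falls
#' strictly inside it (`start < pges_end < start + 10`); a transition on the
#' window boundary counts as not contained. Starts are drawn uniformly
#' within each class, without replacement while distinct starts last, so up
#' to `n_per_class` snippets per class are returned. Recordings without an
#' annotation yield negatives only.
#'
#' @param rec A montaged [recording()] at 200 Hz.
#' @param n_per_class Number of snippets requested per class.
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#' @return A list of [snippet()] objects (possibly empty, with a warning,
#'   for recordings shorter than 10 s).
#' @export
extract_snippets <- function(rec, n_per_class, rng_seed) {
  stopifnot(inherits(rec, "pges_recording"))
  dur <- recording_duration(rec)
  if (dur < snippet_duration_s) {
    warning(sprintf("recording '%s' shorter than %g s; no snippets extracted",
                    rec$patient_id, snippet_duration_s))
    return(list())
  }
  win_n <- as.integer(round(snippet_duration_s * rec$fs))
  max_start_idx <- nrow(rec$samples) - win_n       # 0-based sample-grid starts
  all_starts <- 0:max_start_idx
  start_times <- all_starts / rec$fs
  pe <- rec$pges_end_s
  if (is.null(pe)) {
    pos_starts <- integer(0)
    neg_starts <- all_starts
  } else {
    is_pos <- start_times < pe & pe < start_times + snippet_duration_s
    pos_starts <- all_starts[is_pos]
    neg_starts <- all_starts[!is_pos]
  }
  draw <- function(pool, n) {
    if (length(pool) == 0 || n == 0) return(integer(0))
    if (length(pool) >= n) sample(pool, n)
    else sample(pool, n, replace = TRUE)
  }
  with_seed(rng_seed, {
    chosen_pos <- draw(pos_starts, n_per_class)
    chosen_neg <- draw(neg_starts, n_per_class)
    c(
      lapply(chosen_pos, function(s0) {
        snippet(rec$samples[s0 + seq_len(win_n), , drop = FALSE], rec$fs,
                1L, rec$patient_id, s0 / rec$fs)
      }),
      lapply(chosen_neg, function(s0) {
        snippet(rec$samples[s0 + seq_len(win_n), , drop = FALSE], rec$fs,
                0L, rec$patient_id, s0 / rec$fs)
      }))
  })
}
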