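# 127-dimensional feature representation of a 10-s snippet, built from five
# families: inter-channel Pearson correlations (45), temporal signal ratios
# (24), their slow-wave (3-8 Hz) variants (24), slow-wave signal statistics
# (22) and sliding signal differences (12). For k channels the counts are
# C(k,2), 2k+4, 2k+4, 2k+2 and k+2, i.e. C(k,2) + 7k + 12 in total.
#
# All features reduce to a correlation matrix plus per-channel statistics,
# so they are computed once per snippet (snippet_stats) and assembled per
# channel/family subset (features_from_stats); channel subsetting commutes
# with the per-channel filters, which makes the two routes identical.

feature_families <- c("correlation", "temporal_ratio",
                      "lowfreq_temporal_ratio", "lowfreq_signal",
                      "sliding_difference")

# All ratios and normalizations share one denominator guard: a denominator
# within eps of zero (in uV or uV^2) makes the feature 0, keeping classifier
# input finite and deterministic. Zero-mean EEG makes near-zero first-half
# means routine, so this convention matters and is documented.
.pges_eps <- 1e-12

guard_div <- function(num, den) ifelse(abs(den) < .pges_eps, 0, num / den)

# population variance (divide by N); ratios are insensitive to the choice,
# the raw variance features are not, so it is fixed here
var_pop <- function(x) mean((x - mean(x))^2)

# correlation matrix with zero-variance channels mapped to 0 off-diagonal
safe_cor <- function(x) {
  n <- ncol(x)
  ok <- apply(x, 2, stats::sd) > .pges_eps
  cm <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  if (sum(ok) >= 2) cm[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  diag(cm) <- 1
  cm
}

# first-half / last-half ratio statistics per channel of a sample matrix
half_ratio_stats <- function(x) {
  half <- nrow(x) %/% 2
  first <- x[seq_len(half), , drop = FALSE]
  last <- x[(half + 1):(2 * half), , drop = FALSE]
  list(mean_ratio = guard_div(colMeans(last), colMeans(first)),
       var_ratio = guard_div(apply(last, 2, var_pop),
                             apply(first, 2, var_pop)),
       full_var = apply(x, 2, var_pop))
}

# maximum over sliding windows (50 samples, step 10, fully contained) of
# sum(last 25) - sum(first 25)
sliding_max_diff <- function(x) {
  n <- length(x)
  if (n < 50) stop_argument("sliding difference needs at least 50 samples")
  cs <- c(0, cumsum(x))
  starts <- seq(0, n - 50, by = 10)
  first <- cs[starts + 26] - cs[starts + 1]
  last <- cs[starts + 51] - cs[starts + 26]
  max(last - first)
}

#' Per-snippet feature statistics
#'
#' Computes everything the five feature families need -- the inter-channel
#' correlation matrix of the denoised snippet plus per-channel statistics
#' of the denoised and of the 3--8 Hz filtered signal -- once per snippet.
#' [features_from_stats()] then assembles feature vectors for any channel
#' and family subset without re-filtering, which is what makes the channel
#' ablation experiments affordable.
#'
#' @param s A [snippet()] at 200 Hz.
#' @param denoise Apply the 1--47 Hz noise filter first (default `TRUE`;
#'   `FALSE` is used by the noise-filter ablation).
#' @return An object of class `pges_snippet_stats`.
#' @export
snippet_stats <- function(s, denoise = TRUE) {
  stopifnot(inherits(s, "pges_snippet"))
  base <- if (denoise) denoise_snippet(s) else s
  lf <- lowfreq_snippet(base)
  hr <- half_ratio_stats(base$samples)
  lhr <- half_ratio_stats(lf$samples)
  structure(
    list(channels = colnames(s$samples),
         cor = safe_cor(base$samples),
         mean_ratio = hr$mean_ratio, var_ratio = hr$var_ratio,
         full_var = hr$full_var,
         lf_mean_ratio = lhr$mean_ratio, lf_var_ratio = lhr$var_ratio,
         lf_full_var = lhr$full_var,
         lf_mean = colMeans(lf$samples),
         lf_var = apply(lf$samples, 2, var_pop),
         sdiff = apply(lf$samples, 2, sliding_max_diff),
         label = s$label, patient_id = s$patient_id, start_s = s$start_s),
    class = "pges_snippet_stats")
}

# per-channel value + variance-normalized summaries (sum across channels
# and the least-variance channel's value), the pattern all families share
with_summaries <- function(vals, norm_var, prefix) {
  lv <- which.min(norm_var)
  norm <- guard_div(vals, norm_var)
  out <- c(vals, sum(norm), norm[lv])
  names(out) <- c(paste0(prefix, ".", names(vals)),
                  paste0(prefix, ".sum_norm"), paste0(prefix, ".least_var"))
  out
}

#' Assemble a feature vector from precomputed snippet statistics
#'
#' @param st A [snippet_stats()] object.
#' @param families Character subset of the five family names.
#' @param channels Optional channel-name subset (at least 2), in the
#'   snippet's channel order.
#' @return Named numeric feature vector (length `C(k,2) + 7k + 12` for k
#'   channels with all families).
#' @export
features_from_stats <- function(st, families = feature_families,
                                channels = NULL) {
  stopifnot(inherits(st, "pges_snippet_stats"))
  families <- match.arg(families, feature_families, several.ok = TRUE)
  idx <- seq_along(st$channels)
  if (!is.null(channels)) {
    miss <- setdiff(channels, st$channels)
    if (length(miss)) {
      stop_argument(paste("unknown channels:", paste(miss, collapse = ", ")))
    }
    idx <- idx[st$channels %in% channels]       # snippet order preserved
  }
  if (length(idx) < 2) {
    stop_argument("at least two channels are required for feature definition")
  }
  ch <- st$channels[idx]
  out <- numeric(0)
  if ("correlation" %in% families) {
    pairs <- utils::combn(seq_along(idx), 2)
    vals <- st$cor[cbind(idx[pairs[1, ]], idx[pairs[2, ]])]
    names(vals) <- paste0("cor.", ch[pairs[1, ]], "_", ch[pairs[2, ]])
    out <- c(out, vals)
  }
  sub <- function(v) stats::setNames(v[idx], ch)
  if ("temporal_ratio" %in% families) {
    fam <- c(with_summaries(sub(st$mean_ratio), sub(st$full_var), "tmr"),
             with_summaries(sub(st$var_ratio), sub(st$full_var), "tvr"))
    out <- c(out, reorder_ratio_family(fam, ch, "tmr", "tvr"))
  }
  if ("lowfreq_temporal_ratio" %in% families) {
    fam <- c(with_summaries(sub(st$lf_mean_ratio), sub(st$lf_full_var),
                            "lf_tmr"),
             with_summaries(sub(st$lf_var_ratio), sub(st$lf_full_var),
                            "lf_tvr"))
    out <- c(out, reorder_ratio_family(fam, ch, "lf_tmr", "lf_tvr"))
  }
  if ("lowfreq_signal" %in% families) {
    mu <- sub(st$lf_mean)
    v <- sub(st$lf_var)
    lv <- which.min(v)
    norm_mu <- guard_div(mu, v)
    vals <- c(mu, v, sum(norm_mu), norm_mu[lv])
    names(vals) <- c(paste0("lf_mean.", ch), paste0("lf_var.", ch),
                     "lf_mean.sum_norm", "lf_mean.least_var")
    out <- c(out, vals)
  }
  if ("sliding_difference" %in% families) {
    out <- c(out, with_summaries(sub(st$sdiff), sub(st$lf_full_var), "sdiff"))
  }
  out
}

# put a mean/variance ratio family into its canonical layout:
# per-channel mean ratios, per-channel variance ratios, 4 summaries
reorder_ratio_family <- function(vals, ch, mean_prefix, var_prefix) {
  vals[c(paste0(mean_prefix, ".", ch), paste0(var_prefix, ".", ch),
         paste0(mean_prefix, ".sum_norm"),
         paste0(mean_prefix, ".least_var"),
         paste0(var_prefix, ".sum_norm"),
         paste0(var_prefix, ".least_var"))]
}

#' Inter-channel Pearson correlation features
#'
#' One Pearson correlation coefficient per unordered channel pair, ordered
#' lexicographically by channel index (i < j in the snippet's channel
#' order). A zero-variance channel leaves Pearson undefined; such pairs are
#' reported as 0 (no evidence of linear association).
#'
#' @param s A denoised [snippet()] with at least two channels.
#' @return Named numeric vector of length `choose(n_channels, 2)`, names
#'   `cor.<ch_i>_<ch_j>`.
#' @export
correlation_features <- function(s) {
  stopifnot(inherits(s, "pges_snippet"))
  x <- s$samples
  if (ncol(x) < 2) stop_argument("correlation features need at least 2 channels")
  cm <- safe_cor(x)
  pairs <- utils::combn(ncol(x), 2)
  vals <- cm[cbind(pairs[1, ], pairs[2, ])]
  names(vals) <- paste0("cor.", colnames(x)[pairs[1, ]], "_",
                        colnames(x)[pairs[2, ]])
  vals
}

#' Channel with the least full-snippet variance
#'
#' Minimal sample variance over the whole snippet is used as a proxy for the
#' channel least contaminated by noise and artifact; summary features single
#' this channel out. Ties break toward the lowest channel index.
#'
#' @param s A [snippet()].
#' @return Integer channel index (1-based).
#' @export
least_variance_channel <- function(s) {
  stopifnot(inherits(s, "pges_snippet"))
  as.integer(which.min(apply(s$samples, 2, var_pop)))
}

#' Temporal signal ratio features
#'
#' Per channel, the ratio of the last-half statistic to the first-half
#' statistic of the snippet, for mean and for (population) variance, plus
#' four summaries: the sum across channels of the ratio normalized by the
#' channel's full-snippet variance, and that normalized ratio for the
#' least-variance channel -- once for the mean ratio and once for the
#' variance ratio. Ratios and normalizations with near-zero denominators
#' resolve to 0 (see the denominator-guard note in the package overview).
#'
#' @param s A denoised [snippet()].
#' @return Named numeric vector of length `2 * n_channels + 4`: mean
#'   ratios, variance ratios, then the four summaries.
#' @export
temporal_ratio_features <- function(s) {
  stopifnot(inherits(s, "pges_snippet"))
  hr <- half_ratio_stats(s$samples)
  ch <- colnames(s$samples)
  vals <- c(with_summaries(stats::setNames(hr$mean_ratio, ch),
                           stats::setNames(hr$full_var, ch), "tmr"),
            with_summaries(stats::setNames(hr$var_ratio, ch),
                           stats::setNames(hr$full_var, ch), "tvr"))
  reorder_ratio_family(vals, ch, "tmr", "tvr")
}

#' Slow-wave temporal signal ratio features
#'
#' As [temporal_ratio_features()] but computed on the 3--8 Hz filtered
#' snippet, characterizing slow-wave dynamics explicitly.
#'
#' @param s A [snippet()] (filtered to 3--8 Hz internally).
#' @param prefiltered Set to `TRUE` when `s` is already the 3--8 Hz signal.
#' @return Named numeric vector of length `2 * n_channels + 4`, names
#'   prefixed `lf_`.
#' @export
lowfreq_temporal_ratio_features <- function(s, prefiltered = FALSE) {
  stopifnot(inherits(s, "pges_snippet"))
  if (!prefiltered) s <- lowfreq_snippet(s)
  v <- temporal_ratio_features(s)
  names(v) <- paste0("lf_", names(v))
  v
}

#' Slow-wave signal statistics
#'
#' Mean and population variance of the 3--8 Hz signal per channel, plus two
#' summaries: the sum across channels of mean/variance, and mean/variance of
#' the least-variance channel.
#'
#' @inheritParams lowfreq_temporal_ratio_features
#' @return Named numeric vector of length `2 * n_channels + 2`.
#' @export
lowfreq_signal_features <- function(s, prefiltered = FALSE) {
  stopifnot(inherits(s, "pges_snippet"))
  if (!prefiltered) s <- lowfreq_snippet(s)
  x <- s$samples
  mu <- colMeans(x)
  v <- apply(x, 2, var_pop)
  lv <- which.min(v)
  norm_mu <- guard_div(mu, v)
  vals <- c(mu, v, sum(norm_mu), norm_mu[lv])
  names(vals) <- c(paste0("lf_mean.", colnames(x)),
                   paste0("lf_var.", colnames(x)),
                   "lf_mean.sum_norm", "lf_mean.least_var")
  vals
}

#' Sliding signal difference features
#'
#' A 50-sample (0.25 s at 200 Hz) window slides over each channel of the
#' 3--8 Hz signal in steps of 10 samples; within each placement the sum of
#' the last 25 samples minus the sum of the first 25 is computed, and the
#' maximum over placements is the channel's feature -- a high-resolution
#' detector of upward level shifts in slow-wave amplitude. Two summaries as
#' in the other families: variance-normalized sum across channels, and the
#' normalized feature of the least-variance channel.
#'
#' @inheritParams lowfreq_temporal_ratio_features
#' @return Named numeric vector of length `n_channels + 2`.
#' @export
sliding_difference_features <- function(s, prefiltered = FALSE) {
  stopifnot(inherits(s, "pges_snippet"))
  if (!prefiltered) s <- lowfreq_snippet(s)
  x <- s$samples
  feat <- apply(x, 2, sliding_max_diff)
  v <- apply(x, 2, var_pop)
  with_summaries(stats::setNames(feat, colnames(x)),
                 stats::setNames(v, colnames(x)), "sdiff")
}

#' Full feature vector of a snippet
#'
#' Concatenates the selected feature families in the fixed order
#' correlation, temporal ratio, slow-wave temporal ratio, slow-wave signal,
#' sliding difference, computed on the selected channels only (summary
#' features are subset-dependent, so features are recomputed, never sliced).
#' The snippet is denoised with the 1--47 Hz bandpass first unless
#' `denoise = FALSE` (used by the noise-filter ablation); the slow-wave
#' families always apply their own 3--8 Hz filter.
#'
#' With all families and k channels the vector has length
#' `choose(k, 2) + 7 * k + 12`; for the default 10-channel montage, 127.
#'
#' @param s A [snippet()] at 200 Hz.
#' @param families Character subset of
#'   `c("correlation", "temporal_ratio", "lowfreq_temporal_ratio",
#'   "lowfreq_signal", "sliding_difference")`.
#' @param channels Optional character vector of channel names to restrict
#'   to (at least 2); default all channels of the snippet.
#' @param denoise Apply the 1--47 Hz noise filter first (default `TRUE`).
#' @return Named numeric vector, the feature vector.
#' @export
extract_all <- function(s, families = feature_families, channels = NULL,
                        denoise = TRUE) {
  features_from_stats(snippet_stats(s, denoise = denoise), families, channels)
}

#' Feature table for a set of snippets
#'
#' Applies [extract_all()] to every snippet and assembles one row per
#' snippet with `label`, `patient_id` and `start_s` metadata columns in
#' front of the feature columns. A list of precomputed [snippet_stats()]
#' is accepted in place of snippets, which the experiment runners use to
#' avoid re-filtering per condition.
#'
#' @param snippets List of [snippet()] or [snippet_stats()] objects.
#' @inheritParams extract_all
#' @return A data frame with metadata plus feature columns.
#' @export
featurize_snippets <- function(snippets, families = feature_families,
                               channels = NULL, denoise = TRUE) {
  if (length(snippets) == 0) stop_argument("no snippets to featurize")
  stats_list <- lapply(snippets, function(s) {
    if (inherits(s, "pges_snippet_stats")) s
    else snippet_stats(s, denoise = denoise)
  })
  template <- features_from_stats(stats_list[[1]], families, channels)
  feats <- t(vapply(stats_list, features_from_stats, template,
                    families = families, channels = channels))
  meta <- data.frame(
    label = vapply(stats_list, function(s) s$label, integer(1)),
    patient_id = vapply(stats_list, function(s) as.character(s$patient_id),
                        character(1)),
    start_s = vapply(stats_list, function(s) s$start_s, numeric(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}

#' Names of the feature columns of a feature table
#'
#' @param tbl A data frame from [featurize_snippets()].
#' @return Character vector of the non-metadata column names.
#' @export
feature_columns <- function(tbl) {
  setdiff(names(tbl), c("label", "patient_id", "start_s"))
}
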