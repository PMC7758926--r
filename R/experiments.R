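# Ablation experiment harness: every condition refits the classifier on the
# training-side snippets and evaluates on the held-out patients, identical
# in everything except the feature columns (feature families, noise filter,
# channel subset) that the condition varies. Per-condition seeds are derived
# deterministically from the master seed and the condition label so rows are
# independent yet reproducible.

# precompute per-snippet statistics once so each condition only reassembles
# feature columns instead of re-filtering every snippet
prepare_sides <- function(dataset, denoise = TRUE) {
  list(train = lapply(dataset$train, snippet_stats, denoise = denoise),
       test = lapply(dataset$test, snippet_stats, denoise = denoise))
}

eval_condition <- function(sides, families = feature_families,
                           channels = NULL, n_trees = 501L, seed = 1L) {
  tr <- featurize_snippets(sides$train, families, channels)
  te <- featurize_snippets(sides$test, families, channels)
  fcols <- feature_columns(tr)
  m <- train_classifier(tr[fcols], tr$label, n_trees = n_trees,
                        rng_seed = seed)
  scores <- predict_score(m, te[fcols])
  ev <- roc_auc(scores, te$label)
  list(auc = ev$auc, precision = ev$precision, recall = ev$recall,
       f1 = ev$f1, n_features = length(fcols), eval = ev)
}

report_row <- function(condition, res, seed, meta = "") {
  data.frame(condition = condition, auc = res$auc, precision = res$precision,
             recall = res$recall, f1 = res$f1, n_features = res$n_features,
             seed = seed, meta = meta, stringsAsFactors = FALSE)
}

as_report <- function(rows, kind) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pges_report", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.pges_report <- function(x, ...) {
  cat(sprintf("experiment report (%s): %d conditions\n",
              attr(x, "kind"), nrow(x)))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

check_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pges_dataset"))
  if (length(dataset$train) == 0 || length(dataset$test) == 0) {
    stop_argument("dataset must have snippets on both sides of the split")
  }
}

#' Feature-family ablation experiment
#'
#' Trains and evaluates one classifier per feature-family subset, all else
#' identical, to measure how much each family contributes on its own.
#'
#' @param dataset A patient-disjoint [generate_dataset()] result.
#' @param families List of character vectors, one condition per entry;
#'   defaults to the five single families plus the full set. Duplicates
#'   within an entry are dropped with a warning.
#' @param n_trees Trees per forest (default 501).
#' @param seed Master seed; per-condition seeds derive from it.
#' @return A `pges_report` data frame with one row per subset.
#' @export
run_feature_subset_experiment <- function(dataset,
                                          families = NULL,
                                          n_trees = 501L, seed = 1L) {
  check_dataset(dataset)
  if (is.null(families)) {
    families <- c(as.list(feature_families), list(feature_families))
  }
  if (length(families) == 0) stop_argument("no feature-family subsets given")
  sides <- prepare_sides(dataset)
  rows <- lapply(families, function(fam) {
    if (length(fam) == 0) stop_argument("empty feature-family subset")
    if (anyDuplicated(fam)) {
      warning("duplicate families in subset; deduplicated")
      fam <- unique(fam)
    }
    fam <- match.arg(fam, feature_families, several.ok = TRUE)
    label <- paste(fam, collapse = "+")
    cseed <- derive_seed(seed, label)
    res <- eval_condition(sides, families = fam, n_trees = n_trees,
                          seed = cseed)
    report_row(label, res, cseed)
  })
  as_report(rows, "feature_subsets")
}

#' Noise-filter ablation experiment
#'
#' Evaluates the correlation + temporal-ratio feature set with and without
#' the 1--47 Hz noise filter (the slow-wave families are excluded because
#' their 3--8 Hz band filters implicitly). On noisy data the filtered
#' condition is expected to score at least as well.
#'
#' @inheritParams run_feature_subset_experiment
#' @return A `pges_report` with rows `filter_on` and `filter_off`.
#' @export
run_filter_ablation <- function(dataset, n_trees = 501L, seed = 1L) {
  check_dataset(dataset)
  fam <- c("correlation", "temporal_ratio")
  rows <- lapply(c("filter_on", "filter_off"), function(cond) {
    cseed <- derive_seed(seed, cond)
    sides <- prepare_sides(dataset, denoise = (cond == "filter_on"))
    res <- eval_condition(sides, families = fam,
                          n_trees = n_trees, seed = cseed)
    report_row(cond, res, cseed, meta = paste(fam, collapse = "+"))
  })
  as_report(rows, "filter_ablation")
}

#' Default scalp-region channel groups
#'
#' @return Named list: left (FP1, F7, T7, P7), right (FP2, F8, T8, P8),
#'   center (Fz, Cz) and the diametric pair (FP1, P8).
#' @export
default_regions <- function() {
  list(left = c("FP1", "F7", "T7", "P7"),
       right = c("FP2", "F8", "T8", "P8"),
       center = c("Fz", "Cz"),
       diametric = c("FP1", "P8"))
}

#' Channel-subset experiments
#'
#' Three modes, each refitting per condition with features recomputed on
#' the channel subset (pair features and summaries are subset-dependent):
#' \describe{
#'   \item{regions}{one condition per named channel group
#'     (`params$regions`, default [default_regions()]).}
#'   \item{sequences}{for each channel ordering in `params$sequences`
#'     (default: `params$n_sequences` seeded random orderings, 5), one
#'     condition per prefix length 2..n -- how performance grows as
#'     channels are added.}
#'   \item{combinations}{every `choose(10, k)` channel combination for
#'     `k = params$k` (2 or 3), ranked by AUC.}
#' }
#'
#' @inheritParams run_feature_subset_experiment
#' @param mode One of `"regions"`, `"sequences"`, `"combinations"`.
#' @param params Mode-specific parameter list (see Details).
#' @return A `pges_report`; sequences rows carry `sequence` and
#'   `n_channels` metadata, combinations rows a `rank` column.
#' @export
run_channel_experiments <- function(dataset,
                                    mode = c("regions", "sequences",
                                             "combinations"),
                                    params = list(), n_trees = 501L,
                                    seed = 1L) {
  check_dataset(dataset)
  mode <- match.arg(mode)
  chans <- colnames(dataset$train[[1]]$samples)
  sides <- prepare_sides(dataset)
  run_one <- function(label, channels, meta = "") {
    cseed <- derive_seed(seed, label)
    res <- eval_condition(sides, channels = channels, n_trees = n_trees,
                          seed = cseed)
    report_row(label, res, cseed, meta = meta)
  }
  if (mode == "regions") {
    regions <- if (is.null(params$regions)) default_regions() else
      params$regions
    rows <- lapply(names(regions), function(nm) {
      run_one(nm, regions[[nm]], meta = paste(regions[[nm]], collapse = ","))
    })
    return(as_report(rows, "regions"))
  }
  if (mode == "sequences") {
    sequences <- params$sequences
    if (is.null(sequences)) {
      n_seq <- if (is.null(params$n_sequences)) 5L else params$n_sequences
      sequences <- with_seed(derive_seed(seed, "sequences"),
                             lapply(seq_len(n_seq),
                                    function(i) sample(chans)))
    }
    rows <- list()
    for (i in seq_along(sequences)) {
      sq <- sequences[[i]]
      for (k in seq_along(sq)) {
        if (k < 2) next                 # single channel: features undefined
        label <- sprintf("seq%d_k%d", i, k)
        row <- run_one(label, sq[seq_len(k)],
                       meta = paste(sq[seq_len(k)], collapse = ","))
        row$sequence <- i
        row$n_channels <- k
        rows[[length(rows) + 1]] <- row
      }
    }
    return(as_report(rows, "sequences"))
  }
  k <- params$k
  if (is.null(k) || !k %in% c(2, 3)) {
    stop_argument("combinations mode needs params$k in {2, 3}")
  }
  combos <- utils::combn(chans, k, simplify = FALSE)
  rows <- lapply(combos, function(cc) {
    run_one(paste(cc, collapse = ","), cc)
  })
  rep <- as_report(rows, sprintf("combinations_k%d", k))
  rep <- rep[order(-rep$auc), ]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  rep
}

#' Class-conditional summary of correlation features
#'
#' For every correlation feature involving `anchor_channel`, reports the
#' mean and standard deviation within the positive (contains end of PGES)
#' and negative classes, plus the pooled per-class mean and sd over those
#' features. Positives are expected to show higher inter-channel
#' correlation, since the transition out of suppression appears on most
#' channels at once.
#'
#' @param dataset A labeled [generate_dataset()] result (train and test
#'   snippets are pooled).
#' @param anchor_channel Channel name anchoring the feature set
#'   (default `"Fz"`).
#' @return List with `per_feature` (data frame: feature, class means/sds)
#'   and `pooled` (data frame: class, mean, sd, n).
#' @export
feature_distribution_report <- function(dataset, anchor_channel = "Fz") {
  stopifnot(inherits(dataset, "pges_dataset"))
  snips <- c(dataset$train, dataset$test)
  if (length(snips) == 0) stop_argument("empty dataset")
  chans <- colnames(snips[[1]]$samples)
  if (!anchor_channel %in% chans) {
    stop_argument(sprintf("unknown channel '%s'", anchor_channel))
  }
  labels <- vapply(snips, function(s) s$label, integer(1))
  if (length(unique(labels)) < 2) {
    stop_metric("both classes must be present in the dataset")
  }
  feats <- t(vapply(snips, function(s)
    correlation_features(denoise_snippet(s)),
    correlation_features(denoise_snippet(snips[[1]]))))
  pat <- sprintf("(^cor\\.%s_)|(_%s$)", anchor_channel, anchor_channel)
  sel <- grepl(pat, colnames(feats))
  feats <- feats[, sel, drop = FALSE]
  per_feature <- data.frame(
    feature = colnames(feats),
    mean_neg = apply(feats[labels == 0L, , drop = FALSE], 2, mean),
    sd_neg = apply(feats[labels == 0L, , drop = FALSE], 2, stats::sd),
    mean_pos = apply(feats[labels == 1L, , drop = FALSE], 2, mean),
    sd_pos = apply(feats[labels == 1L, , drop = FALSE], 2, stats::sd),
    stringsAsFactors = FALSE)
  rownames(per_feature) <- NULL
  pooled <- data.frame(
    class = c("negative", "positive"),
    mean = c(mean(feats[labels == 0L, ]), mean(feats[labels == 1L, ])),
    sd = c(stats::sd(as.numeric(feats[labels == 0L, ])),
           stats::sd(as.numeric(feats[labels == 1L, ]))),
    n = c(sum(labels == 0L), sum(labels == 1L)),
    stringsAsFactors = FALSE)
  list(per_feature = per_feature, pooled = pooled,
       anchor_channel = anchor_channel)
}
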