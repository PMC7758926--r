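#' Train the random-forest snippet classifier
#'
#' Fits a random forest of `n_trees` classification trees (default 501) on
#' a snippet feature table. Each tree is grown on a bootstrap sample with a
#' random subset of features at every split (`sqrt(p)` features, the
#' standard default); only the tree count is treated as a tuned
#' hyperparameter. Training is deterministic given `rng_seed`.
#'
#' @param features Data frame or matrix of feature columns only (one row
#'   per snippet); all values must be finite.
#' @param labels Binary vector (0/1), one per row.
#' @param n_trees Number of trees (default 501).
#' @param rng_seed Integer seed.
#' @return An object of class `pges_model` with elements `forest` (the
#'   fitted randomForest), `feature_names`, `n_trees` and `train_meta`.
#' @export
train_classifier <- function(features, labels, n_trees = 501L, rng_seed = 1L) {
  features <- as.data.frame(features)
  if (length(labels) != nrow(features)) {
    stop_argument("labels must have one entry per feature row")
  }
  if (nrow(features) < 4) stop_argument("need at least 2 rows per class")
  bad <- names(features)[!vapply(features, function(col)
    all(is.finite(col)), logical(1))]
  if (length(bad)) {
    stop_schema(paste("non-finite feature values in column(s):",
                      paste(bad, collapse = ", ")))
  }
  if (length(unique(labels)) < 2) {
    stop_argument("training labels contain a single class")
  }
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  forest <- with_seed(rng_seed,
    randomForest::randomForest(x = features, y = y,
                               ntree = as.integer(n_trees)))
  structure(
    list(forest = forest, feature_names = names(features),
         n_trees = as.integer(n_trees),
         train_meta = list(
           seed = as.integer(rng_seed), n_rows = nrow(features),
           n_pos = sum(y == "1"), n_neg = sum(y == "0"),
           fingerprint = dataset_fingerprint(features, labels))),
    class = "pges_model")
}

# cheap order-sensitive checksum of the training data
dataset_fingerprint <- function(features, labels) {
  v <- c(as.numeric(as.matrix(features)), as.numeric(labels))
  sprintf("%.8e", sum(v * seq_along(v) %% 97) + length(v))
}

#' @export
print.pges_model <- function(x, ...) {
  cat(sprintf(
    "Random-forest end-of-PGES classifier: %d trees, %d features\n",
    x$n_trees, length(x$feature_names)))
  cat(sprintf("  trained on %d snippets (%d positive / %d negative), seed %d\n",
              x$train_meta$n_rows, x$train_meta$n_pos, x$train_meta$n_neg,
              x$train_meta$seed))
  invisible(x)
}

#' Score snippets with a trained classifier
#'
#' Returns, per row, the fraction of trees voting for the positive class
#' (snippet contains the end of PGES), a score in \[0, 1\] suitable for ROC
#' analysis. The feature columns must match the training columns exactly,
#' including order.
#'
#' @param m A `pges_model` from [train_classifier()].
#' @param features Feature table with columns identical to
#'   `m$feature_names`.
#' @return Numeric score vector in \[0, 1\], one per row.
#' @export
predict_score <- function(m, features) {
  stopifnot(inherits(m, "pges_model"))
  features <- as.data.frame(features)
  if (!identical(names(features), m$feature_names)) {
    stop_schema("feature names/order differ from the model's training columns")
  }
  if (nrow(features) == 0) return(numeric(0))
  votes <- stats::predict(m$forest, newdata = features, type = "prob")
  as.numeric(votes[, "1"])
}

#' @export
predict.pges_model <- function(object, newdata, ...) {
  predict_score(object, newdata)
}

.model_format_version <- 1L

#' Persist a trained classifier
#'
#' The model is written as a single versioned binary payload with an
#' embedded JSON header (feature names, seed, tree count) so files can be
#' inspected and version-checked before the forest itself is deserialized.
#'
#' @param m A `pges_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "pges_model"))
  header <- jsonlite::toJSON(
    list(format = "pges_model", version = .model_format_version,
         n_trees = m$n_trees, seed = m$train_meta$seed,
         feature_names = m$feature_names),
    auto_unbox = TRUE)
  payload <- list(header = as.character(header), model = m)
  ok <- tryCatch({saveRDS(payload, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write model to '%s'", path))
  invisible(path)
}

#' Load a persisted classifier
#'
#' @param path Path written by [save_model()].
#' @return The `pges_model`; predictions after a save/load round trip are
#'   bitwise identical.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_persistence(sprintf("no such file: %s", path))
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_persistence(
                        sprintf("corrupt model file '%s'", path)))
  if (!is.list(payload) || is.null(payload$header) ||
      !inherits(payload$model, "pges_model")) {
    stop_persistence(sprintf("'%s' is not a classifier file", path))
  }
  header <- tryCatch(jsonlite::fromJSON(payload$header),
                     error = function(e) stop_persistence(
                       sprintf("unreadable header in '%s'", path)))
  if (!identical(header$format, "pges_model") ||
      !identical(as.integer(header$version), .model_format_version)) {
    stop_persistence(sprintf(
      "unsupported model format/version in '%s'", path))
  }
  payload$model
}
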