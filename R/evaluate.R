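#' ROC curve and AUC for scored snippets
#'
#' Builds the ROC by sweeping every distinct score threshold; tied scores
#' form a single block traversed by one line segment, so the trapezoidal
#' area equals the Mann-Whitney statistic (probability that a random
#' positive outscores a random negative, ties counting one half).
#' Precision, recall and F1 at the operating threshold are included.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Operating threshold for precision/recall/F1
#'   (default 0.5, predicted positive when score >= threshold).
#' @return An object of class `pges_eval` with `roc_points` (data frame of
#'   fpr, tpr), `auc`, `precision`, `recall`, `f1`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop_argument("scores and labels must have equal length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_metric("both classes must be present to compute ROC/AUC")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  block_end <- c(which(diff(s) != 0), length(s))   # last index of each tie block
  tpr <- c(0, tp[block_end] / n_pos)
  fpr <- c(0, fp[block_end] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pr <- prf(scores, labels, threshold)
  structure(
    list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
         precision = pr$precision, recall = pr$recall, f1 = pr$f1,
         precision_flagged = pr$flagged, threshold = threshold,
         n_pos = n_pos, n_neg = n_neg),
    class = "pges_eval")
}

#' @export
print.pges_eval <- function(x, ...) {
  cat(sprintf(
    "snippet classification: AUC %.3f (%d pos / %d neg)\n", x$auc,
    x$n_pos, x$n_neg))
  cat(sprintf("  at threshold %.2f: precision %.3f%s, recall %.3f, F1 %.3f\n",
              x$threshold, x$precision,
              if (x$precision_flagged) " (no predicted positives)" else "",
              x$recall, x$f1))
  invisible(x)
}

#' @export
plot.pges_eval <- function(x, ...) {
  plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
       xlab = "false-positive rate", ylab = "true-positive rate",
       main = sprintf("ROC, AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Precision, recall and F1 at a threshold
#'
#' Standard confusion-matrix definitions with predicted positive when
#' `score >= threshold`. With no predicted positives, precision is
#' undefined and reported as 0 with `flagged = TRUE`.
#'
#' @inheritParams roc_auc
#' @return List with `precision`, `recall`, `f1`, `flagged`.
#' @export
prf <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0 || sum(labels == 0L) == 0) {
    stop_metric("both classes must be present")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  flagged <- (tp + fp) == 0
  precision <- if (flagged) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, flagged = flagged)
}
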