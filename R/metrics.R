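# Ranking and classification metrics for link prediction.

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counting one half (the rank-statistic form of
#' the AUROC).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return Scalar in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision estimator: thresholds sweep the distinct
#' score values from high to low; each threshold contributes its precision
#' weighted by the recall gained there.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels with at least one positive.
#' @return Scalar in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("need at least one positive")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  recall_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

#' F1 score and accuracy at a fixed threshold
#'
#' Scores are binarized at `threshold` (predict positive when
#' `score >= threshold`); F1 uses the 0/0 := 0 convention when no positives
#' are predicted or present.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector `c(f1 = ..., accuracy = ...)`.
#' @export
f1_accuracy <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(f1 = f1, accuracy = mean(pred == labels))
}
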