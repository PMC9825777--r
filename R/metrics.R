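## Task metrics: AUC / PRAUC for the binary tasks, balanced accuracy and
## macro F1 for the three-class task.

#' Area under the ROC curve
#'
#' Rank-based (equivalent to the normalized Mann-Whitney U statistic; tied
#' scores count 1/2).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    bs_stop("AUC undefined: only one class present in labels")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over score thresholds (tied scores grouped)
#' of precision times the recall increment.  A constant classifier scores
#' the positive prevalence; a perfect one scores 1.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels with at least one positive.
#' @return PRAUC in `(0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) bs_stop("PRAUC undefined: no positive labels")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Balanced accuracy (mean per-class recall)
#' @param predicted Hard class predictions.
#' @param labels True class labels.
#' @return Mean recall over the classes present in `labels`.
#' @export
balanced_accuracy <- function(predicted, labels) {
  classes <- sort(unique(labels))
  mean(vapply(classes, function(cl)
    mean(predicted[labels == cl] == cl), 0))
}

#' Macro-averaged F1 score
#'
#' Per-class F1 (0 when a class is never predicted or never recalled),
#' averaged over the classes present in `labels`.
#' @param predicted Hard class predictions.
#' @param labels True class labels.
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(predicted, labels) {
  classes <- sort(unique(labels))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & labels == cl)
    fp <- sum(predicted == cl & labels != cl)
    fn <- sum(predicted != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

#' Evaluate classifier scores on one of the three tasks
#'
#' Tasks A and B (binary: cell-A-specific vs cell-B-specific, and specific
#' vs shared) report AUC and PRAUC from the positive-class score; task C
#' (three-way) reports balanced accuracy and macro F1 with hard labels by
#' row-wise argmax.
#'
#' @param scores For tasks A/B a numeric vector of positive-class scores;
#'   for task C an n x 3 matrix of class probabilities.
#' @param labels Integer labels: 0/1 (A, B) or 0/1/2 (C).
#' @param task `"A"`, `"B"` or `"C"`.
#' @return Named list of metrics.
#' @export
evaluate <- function(scores, labels, task = c("B", "A", "C")) {
  task <- match.arg(task)
  if (task %in% c("A", "B")) {
    stopifnot(length(scores) == length(labels))
    list(auc = auc_roc(scores, labels), prauc = auc_pr(scores, labels))
  } else {
    stopifnot(is.matrix(scores), ncol(scores) == 3,
              nrow(scores) == length(labels))
    hard <- max.col(scores, ties.method = "first") - 1L
    list(balanced_accuracy = balanced_accuracy(hard, as.integer(labels)),
         macro_f1 = macro_f1(hard, as.integer(labels)))
  }
}
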