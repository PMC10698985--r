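#' Confusion counts from scores
#'
#' Thresholds scores (call = score >= threshold; a score exactly at the
#' threshold is a positive call) and counts true/false positives and
#' negatives.
#'
#' @param labels 0/1 labels.
#' @param scores Predicted scores.
#' @param threshold Decision threshold (default 0.5).
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  calls <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  list(TP = sum(calls == 1L & labels == 1L),
       TN = sum(calls == 0L & labels == 0L),
       FP = sum(calls == 1L & labels == 0L),
       FN = sum(calls == 0L & labels == 1L))
}

#' Scalar classification metrics
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from confusion counts. Any metric whose denominator is
#' zero is reported as 0 so heavily imbalanced runs remain reportable.
#'
#' @param c Confusion counts (list with `TP`, `TN`, `FP`, `FN`).
#' @return Named list: `ACC`, `Pre`, `Rec`, `F1`, `MCC`.
#' @export
scalar_metrics <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("no scored samples", call. = FALSE)
  div0 <- function(num, den) if (den == 0) 0 else num / den
  pre <- div0(TP, TP + FP)
  rec <- div0(TP, TP + FN)
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  list(ACC = div0(TP + TN, total),
       Pre = pre,
       Rec = rec,
       F1 = div0(2 * pre * rec, pre + rec),
       MCC = if (mcc_den == 0) 0 else
         (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation; tied scores contribute half.
#'
#' @param labels 0/1 labels (both classes required).
#' @param scores Predicted scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)                      # average ranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision: the mean, over positives, of the precision at the
#' rank of each positive after sorting scores in decreasing order
#' (step-wise integration of the precision-recall curve, no
#' interpolation).
#'
#' @param labels 0/1 labels (both classes required).
#' @param scores Predicted scores.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0 || sum(labels == 0L) == 0) {
    stop("AUPRC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec_at_k <- cumsum(y) / seq_along(y)
  sum(prec_at_k[y == 1L]) / n_pos
}

#' Per-class accuracy
#'
#' Accuracy of the positive (interaction-site) class — identical to
#' recall — and of the negative class (specificity).
#'
#' @param labels 0/1 labels (both classes required).
#' @param calls 0/1 predicted calls.
#' @return List with `acc_pos` and `acc_neg`.
#' @export
per_class_accuracy <- function(labels, calls) {
  labels <- as.integer(labels)
  calls <- as.integer(calls)
  if (length(labels) != length(calls)) {
    stop("labels and calls differ in length", call. = FALSE)
  }
  if (sum(labels == 1L) == 0 || sum(labels == 0L) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  list(acc_pos = sum(calls == 1L & labels == 1L) / sum(labels == 1L),
       acc_neg = sum(calls == 0L & labels == 0L) / sum(labels == 0L))
}

#' Full evaluation of scored residues
#'
#' Convenience wrapper computing the seven headline metrics plus the
#' per-class accuracies at a threshold.
#'
#' @param labels 0/1 labels.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row data frame: ACC, Pre, Rec, F1, MCC, AUROC, AUPRC,
#'   acc_pos, acc_neg.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_from_scores(labels, scores, threshold)
  m <- scalar_metrics(cc)
  pc <- per_class_accuracy(labels, as.integer(scores >= threshold))
  data.frame(ACC = m$ACC, Pre = m$Pre, Rec = m$Rec, F1 = m$F1, MCC = m$MCC,
             AUROC = auroc(labels, scores), AUPRC = auprc(labels, scores),
             acc_pos = pc$acc_pos, acc_neg = pc$acc_neg)
}
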