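#' Confusion counts at a score threshold
#'
#' A pair is predicted positive when its score is `>= threshold`.
#'
#' @param scores numeric scores.
#' @param labels binary labels of equal length.
#' @param threshold decision threshold (default 0.5).
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Accuracy: (TP + TN) / (TP + TN + FP + FN)
#' @param c a [confusion()] object.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("empty confusion table")
  (c$tp + c$tn) / total
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' When any factor of the denominator is zero the coefficient is undefined;
#' by convention it is reported as 0 with a warning.
#'
#' @param c a [confusion()] object.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    warning("MCC denominator has a zero factor; reporting 0 by convention")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision: TP / (TP + FP)
#'
#' Undefined (reported as `NaN` with a warning) when nothing is predicted
#' positive.
#'
#' @param c a [confusion()] object.
#' @return precision in `[0, 1]`, or `NaN`.
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) {
    warning("precision undefined: no pair predicted positive")
    return(NaN)
  }
  c$tp / (c$tp + c$fp)
}

#' Recall (sensitivity, TPR): TP / (TP + FN)
#' @param c a [confusion()] object.
#' @return recall in `[0, 1]`.
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) stop("recall undefined: no positive labels")
  c$tp / (c$tp + c$fn)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ranking metric")
  }
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) form: the probability that a random
#' positive outscores a random negative, with tied scores counted as half
#' concordant. Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric scores.
#' @param labels binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the ranked list (average precision): tied score
#' groups are processed as one step, and each step contributes its recall
#' increment times the precision at the end of the step.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels == 1)
  sum(diff(c(0, rec)) * prec)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold, with the (0, 0)
#' origin prepended; suitable for trapezoidal plotting.
#'
#' @inheritParams roc_auc
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  ends <- cumsum(rle(s)$lengths)
  data.frame(fpr = c(0, cumsum(1 - y)[ends] / sum(labels == 0)),
             tpr = c(0, cumsum(y)[ends] / sum(labels == 1)))
}

#' Precision-recall curve points
#' @inheritParams roc_auc
#' @return data frame with columns `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[ends]
  fp <- cumsum(1 - y)[ends]
  data.frame(recall = tp / sum(labels == 1), precision = tp / (tp + fp))
}
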