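# Confusion-table metrics (sensitivity, specificity, accuracy, balanced
# accuracy, MCC) and curve areas (ROC-AUC, PR-AUC). Drivers are the
# positive class throughout.

#' Classification metrics for driver/passenger predictions
#'
#' Computes the confusion counts and derived rates:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`, balanced accuracy `(sensitivity+specificity)/2` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' factor of the denominator is 0). When probabilities are supplied,
#' ROC-AUC (trapezoidal integration of the ROC curve; ties share credit)
#' and PR-AUC (step integration of the precision-recall curve) are added.
#' A single-class truth leaves the curve areas `NA` with
#' `auc_defined = FALSE`.
#'
#' @param labels True binary labels (driver = 1).
#' @param predictions Predicted binary labels.
#' @param probabilities Optional predicted driver probabilities.
#' @return A `MetricsReport` list with `TP`, `TN`, `FP`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`, `mcc`,
#'   `auc_roc`, `auc_pr`, `auc_defined`, `n`.
#' @export
classification_metrics <- function(labels, predictions,
                                   probabilities = NULL) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions))
  TP <- sum(labels == 1L & predictions == 1L)
  TN <- sum(labels == 0L & predictions == 0L)
  FP <- sum(labels == 0L & predictions == 1L)
  FN <- sum(labels == 1L & predictions == 0L)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  sens <- rate(TP, TP + FN)
  spec <- rate(TN, TN + FP)
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  auc_roc <- auc_pr <- NA_real_
  auc_defined <- FALSE
  if (!is.null(probabilities) && length(unique(labels)) == 2L) {
    auc_roc <- roc_auc(labels, probabilities)
    auc_pr <- pr_auc(labels, probabilities)
    auc_defined <- TRUE
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity = sens, specificity = spec,
                 accuracy = (TP + TN) / length(labels),
                 balanced_accuracy = mean(c(sens, spec)),
                 mcc = mcc, auc_roc = auc_roc, auc_pr = auc_pr,
                 auc_defined = auc_defined, n = length(labels)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport (n=%d): sens %.3f spec %.3f acc %.3f bacc %.3f mcc %.3f",
    x$n, x$sensitivity, x$specificity, x$accuracy, x$balanced_accuracy,
    x$mcc))
  if (x$auc_defined) cat(sprintf(" auc %.3f pr-auc %.3f", x$auc_roc,
                                 x$auc_pr))
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over the unique score
#' thresholds; tied scores share credit, so the value equals the
#' normalised Mann-Whitney U statistic.
#'
#' @param labels True binary labels.
#' @param scores Numeric scores (higher = more driver-like).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1L); neg <- sum(labels == 0L)
  if (pos == 0L || neg == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- tapply(lab == 1L, grp, sum)
  fp <- tapply(lab == 0L, grp, sum)
  tpr <- c(0, cumsum(tp) / pos)
  fpr <- c(0, cumsum(fp) / neg)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Step integration of precision over recall (average precision): walking
#' down the score-sorted predictions, each recall increment contributes
#' the precision at that threshold. Tied scores are processed as one
#' block.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1L)
  if (pos == 0L || all(labels == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp_b <- tapply(lab == 1L, grp, sum)
  n_b <- tapply(lab, grp, length)
  tp_cum <- cumsum(tp_b); n_cum <- cumsum(n_b)
  precision <- tp_cum / n_cum
  recall_inc <- tp_b / pos
  sum(precision * recall_inc)
}
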