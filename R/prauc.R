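#' Area under the precision-recall curve
#'
#' Computes prAUC by step-wise integration of the precision-recall curve
#' (the "average precision" estimator): scores are sorted decreasingly,
#' tied scores are collapsed into a single threshold, and the area is
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over thresholds. For a random scorer the
#' expected value approaches the positive-class fraction, which is why this
#' metric, rather than ROC AUC, is informative on heavily imbalanced
#' DEG/non-DEG data.
#'
#' @param score numeric vector; larger values mean "more likely positive".
#' @param positive logical (or 0/1) vector, `TRUE` for the positive class.
#' @return a single number in \[0, 1\].
#' @export
#' @examples
#' pr_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)) # 1
pr_auc <- function(score, positive) {
  if (length(score) != length(positive))
    stop("`score` and `positive` must have the same length")
  pos <- as.logical(positive)
  if (anyNA(score) || anyNA(pos)) stop("NA values in scores or labels")
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("no positive observations: prAUC undefined")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- pos[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # collapse tied scores: keep the last index of each distinct threshold
  last <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Absolute difference of the two within-class accuracies
#'
#' Within-class accuracy is the number of correct predictions of a class
#' divided by that class's size in the test set; the absolute difference of
#' the DEG and non-DEG values ("diff") is the balance criterion used to pick
#' the best model among those passing the prAUC threshold.
#'
#' @param acc_deg within-class accuracy of the DEG class.
#' @param acc_non within-class accuracy of the non-DEG class.
#' @return `abs(acc_deg - acc_non)`.
#' @export
#' @examples
#' class_accuracy_difference(0.368, 0.693) # 0.325
class_accuracy_difference <- function(acc_deg, acc_non) {
  stopifnot(is.numeric(acc_deg), is.numeric(acc_non))
  abs(acc_deg - acc_non)
}
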