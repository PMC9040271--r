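# Threshold-free classification metrics: AUROC via the rank (midrank)
# statistic, AUPR by precision-recall step integration, F1 at a fixed
# probability cutoff.

#' Area under the ROC curve
#'
#' Computed by the Wilcoxon rank statistic with midranks for tied scores,
#' which equals the fraction of (ON, OFF) gene pairs ranked concordantly,
#' counting ties as one half.
#'
#' @param scores numeric prediction scores (higher = more likely ON).
#' @param labels 0/1 class labels (1 = ON).
#' @return AUROC in [0, 1], or \code{NA} with a warning if only one class
#'   is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over score thresholds
#' (average precision): \eqn{\sum_k (R_k - R_{k-1}) P_k} with thresholds at
#' the distinct score values, processing tied scores as one block.
#'
#' @inheritParams auroc
#' @return AUPR in [0, 1], or \code{NA} with a warning for one-class input.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels)) {
    warning("AUPR undefined: only one class present")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # cut points at the last element of each tied block
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a probability cutoff
#'
#' The ON class (label 1) is the positive class; predicted ON when the
#' score reaches the cutoff (default 0.5 on the probability scale).
#'
#' @inheritParams auroc
#' @param cutoff decision threshold on \code{scores}.
#' @return F1 in [0, 1]; \code{NA} if there are neither true positives nor
#'   any predicted/actual positives.
#' @export
f1_score <- function(scores, labels, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  denom <- 2 * tp + fp + fn
  if (denom == 0L) return(NA_real_)
  2 * tp / denom
}
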