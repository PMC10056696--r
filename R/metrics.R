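#' Confusion counts for binary predictions
#'
#' Standard 2x2 confusion counts with class 1 as the positive class.
#'
#' @param yTrue 0/1 truth vector.
#' @param yPred 0/1 prediction vector of the same length.
#' @return Named list with integer elements `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have the same length")
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    stop("values must be 0/1")
  list(
    tp = sum(yTrue == 1 & yPred == 1),
    fp = sum(yTrue == 0 & yPred == 1),
    tn = sum(yTrue == 0 & yPred == 0),
    fn = sum(yTrue == 1 & yPred == 0)
  )
}

#' Precision, recall, specificity, F1 and accuracy from confusion counts
#'
#' Computes P = TP/(TP+FP), R = TP/(TP+FN), S = TN/(TN+FP),
#' F1 = 2PR/(P+R) and accuracy = (TP+TN)/total, as fractions in \[0, 1\].
#' Any metric whose denominator is zero is returned as `NA` (an explicit
#' undefined marker), never as 0 and never as an error.
#'
#' @param counts a list with elements `tp`, `fp`, `tn`, `fn` (all >= 0, not
#'   all zero), as returned by [confusionCounts()]. Fractional counts are
#'   accepted so printed percentage tables can be checked directly.
#' @return Named list: `precision`, `recall`, `specificity`, `f1`,
#'   `accuracy`.
#' @examples
#' computeMetrics(confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
#' @export
computeMetrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stop("counts are all zero")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  p <- safe(tp, tp + fp)
  r <- safe(tp, tp + fn)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * (p * r) / (p + r)
  list(
    precision = p,
    recall = r,
    specificity = safe(tn, tn + fp),
    f1 = f1,
    accuracy = (tp + tn) / total
  )
}

#' F1 score from precision and recall
#'
#' The harmonic-mean combination 2PR/(P+R) on whatever scale P and R share
#' (fractions or percentages).
#'
#' @param precision precision P.
#' @param recall recall R.
#' @return F1 on the same scale; `NA` when P + R = 0.
#' @examples
#' f1Score(99.15, 92.80)  # percent scale
#' @export
f1Score <- function(precision, recall) {
  if (precision + recall == 0) return(NA_real_)
  2 * (precision * recall) / (precision + recall)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, with ties counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param yTrue 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' aucROC(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
aucROC <- function(scores, yTrue) {
  if (length(scores) != length(yTrue))
    stop("scores and yTrue must have the same length")
  if (!all(yTrue %in% c(0, 1))) stop("yTrue must be 0/1")
  n1 <- sum(yTrue == 1)
  n0 <- sum(yTrue == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[yTrue == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full binary evaluation report
#'
#' @param yTrue 0/1 truth.
#' @param yPred 0/1 predictions.
#' @param scores optional probabilities for the AUC entry.
#' @return Named list with keys `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `specificity`, `f1`, `accuracy` and (when scores are given and
#'   both classes present) `auc`.
#' @export
evaluateBinary <- function(yTrue, yPred, scores = NULL) {
  cc <- confusionCounts(yTrue, yPred)
  out <- c(cc, computeMetrics(cc))
  if (!is.null(scores) && length(unique(yTrue)) == 2L)
    out$auc <- aucROC(scores, yTrue)
  out
}
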