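#' Pearson fitness with degenerate-case handling
#'
#' Pearson correlation between predictions and observations; if either
#' vector is constant (zero variance) the correlation is undefined and 0 is
#' returned with a warning, so that search fitness stays NaN-safe.
#'
#' @param pred,obs numeric vectors.
#' @return correlation in [-1, 1], or 0 for degenerate input.
#' @export
pearson_fitness <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("constant predictions or observations; Pearson undefined, returning 0")
    return(0)
  }
  stats::cor(pred, obs)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision: records are ranked by decreasing score
#' (ties broken by original index, deterministically) and precision is
#' averaged at each positive hit. The headline metric for rare-positive
#' off-target classification.
#'
#' @param score numeric scores, higher = more positive.
#' @param label 0/1 labels.
#' @return scalar in [0, 1].
#' @export
average_precision <- function(score, label) {
  stopifnot(length(score) == length(label))
  P <- sum(label == 1)
  if (P == 0) stop("average precision undefined without positive labels")
  ord <- order(score, seq_along(score), decreasing = c(TRUE, FALSE),
               method = "radix")
  l <- label[ord]
  prec <- cumsum(l) / seq_along(l)
  sum(prec[l == 1]) / P
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with midrank tie handling.
#'
#' @inheritParams average_precision
#' @return scalar in [0, 1].
#' @export
auroc <- function(score, label) {
  pos <- label == 1
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("AUROC needs both classes")
  r <- rank(score)
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}
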