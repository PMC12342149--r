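#' Ranking loss of top-1 decoy selection
#'
#' The true quality of the best decoy in the pool minus the true quality of
#' the decoy the predictor ranks first; 0 means the predictor selected the
#' truly best decoy. Ties in the predicted score are broken toward the
#' lexicographically smallest decoy id (or smallest index when ids are
#' absent) for reproducibility.
#'
#' @param trueScores True quality scores (e.g. TM-scores), optionally
#'   named by decoy id.
#' @param predictedScores Predicted quality scores, same length/order.
#' @return Non-negative scalar ranking loss.
#' @examples
#' rankingLoss(c(0.990, 0.613, 0.987), c(0.2, 0.9, 0.5))  # 0.377
#' @export
rankingLoss <- function(trueScores, predictedScores) {
  stopifnot(length(trueScores) == length(predictedScores))
  if (!length(trueScores)) stop("empty input")
  ids <- names(predictedScores)
  if (is.null(ids)) ids <- sprintf("%09d", seq_along(predictedScores))
  ord <- order(-predictedScores, ids)
  unname(max(trueScores) - trueScores[ord[1L]])
}

#' AUC with 75\%-quantile labeling
#'
#' Divides the decoys into two classes at the 75\% empirical quantile of
#' the true scores (linear-interpolation quantile; true score >= threshold
#' is positive) so the metric focuses on recognizing the better quarter of
#' the pool, and returns the rank-based (Mann-Whitney) area under the ROC
#' curve of the predicted scores with mid-rank tie correction.
#'
#' @inheritParams rankingLoss
#' @return AUC in [0, 1], or \code{NA} with a warning when a class is
#'   empty (all true scores identical).
#' @export
auc75q <- function(trueScores, predictedScores) {
  stopifnot(length(trueScores) == length(predictedScores))
  thr <- quantile(trueScores, 0.75, names = FALSE)
  pos <- trueScores >= thr
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) {
    warning("quantile labeling produced an empty class; AUC undefined")
    return(NA_real_)
  }
  r <- rank(predictedScores)  # mid-ranks on ties
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Pearson and Spearman correlation of predictions with truth
#'
#' @inheritParams rankingLoss
#' @return Named numeric vector \code{c(corr_p = ..., corr_s = ...)};
#'   \code{NA} with a warning when either side has zero variance.
#' @export
correlations <- function(trueScores, predictedScores) {
  stopifnot(length(trueScores) == length(predictedScores))
  if (length(trueScores) < 3L)
    stop("correlations need at least 3 decoys")
  if (sd(trueScores) == 0 || sd(predictedScores) == 0) {
    warning("zero variance; correlations undefined")
    return(c(corr_p = NA_real_, corr_s = NA_real_))
  }
  c(corr_p = cor(trueScores, predictedScores),
    corr_s = cor(trueScores, predictedScores, method = "spearman"))
}

#' Evaluate one target
#'
#' All four per-target metrics in one call.
#'
#' @inheritParams rankingLoss
#' @param targetId Target identifier recorded in the result.
#' @return One-row data.frame: target_id, corr_p, corr_s, ranking_loss,
#'   auc.
#' @export
evaluateTarget <- function(trueScores, predictedScores,
                           targetId = "target") {
  cr <- suppressWarnings(correlations(trueScores, predictedScores))
  data.frame(target_id = targetId,
             corr_p = unname(cr["corr_p"]),
             corr_s = unname(cr["corr_s"]),
             ranking_loss = rankingLoss(trueScores, predictedScores),
             auc = suppressWarnings(auc75q(trueScores, predictedScores)))
}

#' Per-target z-score summation across predictors
#'
#' CASP-style summary: for each target, each predictor's metric value is
#' standardized against the mean and population standard deviation of all
#' predictors on that target, and the per-target z-scores are summed
#' across targets. Loss-type metrics are flipped to \code{1 - loss} before
#' standardization so that higher is always better. Missing
#' predictor-target cells contribute nothing for that predictor on that
#' target; a target with zero variance across predictors contributes z = 0
#' for everyone.
#'
#' @param metricTable Numeric matrix, predictors x targets (dimnames
#'   recommended); \code{NA} marks a predictor that skipped a target.
#' @param lossType Is the metric a loss (flip via \code{1 - x} before
#'   z-scoring)? Default FALSE.
#' @return Named numeric vector of summed z-scores per predictor.
#' @examples
#' m <- rbind(a = c(0.9, 0.8), b = c(0.7, 0.6), c = c(0.5, 0.7))
#' colnames(m) <- c("T1", "T2")
#' zscoreSum(m)
#' @export
zscoreSum <- function(metricTable, lossType = FALSE) {
  stopifnot(is.matrix(metricTable))
  x <- if (lossType) 1 - metricTable else metricTable
  z <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L) { z[, j] <- 0; next }
    mu <- mean(v[ok])
    sdp <- sqrt(mean((v[ok] - mu)^2))  # population SD over predictors
    z[ok, j] <- if (sdp > 0) (v[ok] - mu) / sdp else 0
    z[!ok, j] <- 0
  }
  rowSums(z)
}
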