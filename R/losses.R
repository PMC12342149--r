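#' Training losses
#'
#' The model is trained with a weighted sum of a mean-squared-error loss on
#' absolute quality scores and a pairwise loss on within-subgraph quality
#' differences,
#' \deqn{L_{MSE} = \frac{1}{N}\sum_i (y_i - \hat y_i)^2, \qquad
#'       L_{pair} = \frac{1}{|P|}\sum_{(i,j)\in P}
#'       (\Delta y_{ij} - \Delta\hat y_{ij})^2, \qquad
#'       L = \alpha L_{MSE} + \beta L_{pair},}
#' where \eqn{P} is the set of all unordered decoy pairs within a subgraph
#' and \eqn{\Delta y_{ij} = y_i - y_j}. The pairwise term is invariant to a
#' constant shift of the predictions and drives correct relative ranking.
#'
#' @param yTrue True quality scores.
#' @param yPred Predicted quality scores.
#' @param alpha,beta Non-negative weights of the MSE and pairwise terms.
#' @return Scalar loss value.
#' @examples
#' mseLoss(c(0.2, 0.8), c(0.4, 0.6))       # 0.04
#' pairwiseLoss(c(0.2, 0.8), c(0.4, 0.6))  # 0.16
#' totalLoss(c(0.2, 0.8), c(0.4, 0.6))     # 0.20
#' @export
mseLoss <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred))
  if (!length(yTrue)) stop("empty vectors")
  mean((yTrue - yPred)^2)
}

#' @rdname mseLoss
#' @export
pairwiseLoss <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred))
  n <- length(yTrue)
  if (!n) stop("empty vectors")
  if (n < 2L) {
    warning("single-node subgraph: pairwise loss undefined, contributing 0")
    return(0)
  }
  # sum over unordered pairs of (r_i - r_j)^2 with r = y - yhat expands to
  # n*sum(r^2) - sum(r)^2
  r <- yTrue - yPred
  nP <- n * (n - 1) / 2
  (n * sum(r^2) - sum(r)^2) / nP
}

#' @rdname mseLoss
#' @export
totalLoss <- function(yTrue, yPred, alpha = 1, beta = 1) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0)
  alpha * mseLoss(yTrue, yPred) +
    beta * (if (length(yTrue) >= 2L) pairwiseLoss(yTrue, yPred) else 0)
}

# Gradient of totalLoss w.r.t. yPred (used by the training loop).
.totalLossGrad <- function(yTrue, yPred, alpha = 1, beta = 1) {
  n <- length(yTrue)
  r <- yTrue - yPred
  g <- alpha * (-2 / n) * r
  if (beta > 0 && n >= 2L) {
    nP <- n * (n - 1) / 2
    g <- g + beta * (-2 / nP) * (n * r - sum(r))
  }
  g
}
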