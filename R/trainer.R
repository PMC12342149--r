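#' Training configuration
#'
#' @param optimizer \code{"adamw"} or \code{"sgd"}.
#' @param learningRate Step size (default 1e-3).
#' @param weightDecay Decoupled weight decay (default 1e-5).
#' @param batchSize Subgraphs per optimization step (default 8).
#' @param alpha,beta Loss weights for the MSE and pairwise terms (default 1
#'   each); see [totalLoss()].
#' @param maxEpochs Maximum training epochs (default 50).
#' @param patience Early-stopping patience in non-improving epochs
#'   (default 5).
#' @param seed Integer seed for batch shuffling and dropout.
#' @return A validated list of class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(optimizer = c("adamw", "sgd"),
                           learningRate = 1e-3, weightDecay = 1e-5,
                           batchSize = 8L, alpha = 1, beta = 1,
                           maxEpochs = 50L, patience = 5L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  .assertScalarNumber(learningRate, "learningRate", 1e-12, Inf)
  .assertScalarNumber(weightDecay, "weightDecay", 0, Inf)
  .assertScalarNumber(alpha, "alpha", 0, Inf)
  .assertScalarNumber(beta, "beta", 0, Inf)
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  structure(list(optimizer = optimizer, learningRate = learningRate,
                 weightDecay = weightDecay,
                 batchSize = as.integer(batchSize), alpha = alpha,
                 beta = beta, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' By-target cross-validation splits
#'
#' Partitions targets (never decoys) into \code{nFolds} folds of
#' near-equal size and returns the rotation scheme: in round r, fold r is
#' the test set, the next fold the validation set, and the remaining
#' \code{nFolds - 2} folds the training set. Every target appears in
#' exactly one test fold across rounds.
#'
#' @param targetIds Character vector of target identifiers.
#' @param nFolds Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return List of \code{nFolds} splits, each with \code{foldId},
#'   \code{train}, \code{validation} and \code{test} target-id vectors.
#' @examples
#' sp <- makeCVSplits(sprintf("T%02d", 1:41), nFolds = 10, seed = 1)
#' lengths(lapply(sp, `[[`, "test"))
#' @export
makeCVSplits <- function(targetIds, nFolds = 10L, seed = 1L) {
  targetIds <- as.character(targetIds)
  if (anyDuplicated(targetIds)) stop("duplicate target ids")
  nT <- length(targetIds)
  if (nT < nFolds)
    stop("fewer targets (", nT, ") than folds (", nFolds, ")")
  set.seed(.deriveSeed(seed, 404L))
  shuffled <- sample(targetIds)
  sizes <- rep(nT %/% nFolds, nFolds)
  sizes[seq_len(nT %% nFolds)] <- sizes[seq_len(nT %% nFolds)] + 1L
  folds <- split(shuffled, rep(seq_len(nFolds), times = sizes))
  lapply(seq_len(nFolds), function(r) {
    testF <- r
    valF <- if (r == nFolds) 1L else r + 1L
    list(foldId = r,
         train = unlist(folds[-c(testF, valF)], use.names = FALSE),
         validation = folds[[valF]],
         test = folds[[testF]])
  })
}

.adamwInit <- function(params)
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)

.adamwStep <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .mapParams(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .mapParams(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .mapParams(function(p, m, v)
    p - lr * ((m / c1) / (sqrt(v / c2) + eps) + wd * p),
    params, state$m, state$v)
  list(params = params, state = state)
}

.sgdStep <- function(params, grads, lr, wd)
  .mapParams(function(p, g) p - lr * (g + wd * p), params, grads)

# Mean combined loss of a checkpoint-in-progress over a list of subgraphs
# (evaluation mode).
.evalSubgraphLoss <- function(params, config, subgraphs, labels,
                              alpha, beta) {
  tot <- 0
  for (sub in subgraphs) {
    fw <- .forwardSubgraph(params, config, sub, train = FALSE,
                           keepCache = FALSE)
    y <- labels[[sub$poolKey]][sub$nodes]
    tot <- tot + totalLoss(y, fw$yhat, alpha, beta)
  }
  tot / length(subgraphs)
}

#' Train the graph transformer
#'
#' Mini-batch optimization over sampled subgraphs with the combined
#' MSE + pairwise loss, epoch-end evaluation on the validation subgraphs,
#' checkpoint selection at the minimum validation combined loss, and early
#' stopping. The split is by target: a validation or test target's decoys
#' never enter a training batch (audited before the first epoch).
#'
#' @param trainData,valData Lists of per-target datasets; each element
#'   needs \code{target} (id), \code{subgraphs} (list from
#'   [sampleSubgraphs()]) and \code{labels} (named vector of true
#'   TM-scores over all pool decoys, pool order).
#' @param transformerCfg A [transformerConfig()].
#' @param trainingCfg A [trainingConfig()].
#' @param verbose Print per-epoch losses (default FALSE).
#' @return A checkpoint list with elements \code{params}, \code{config},
#'   \code{nodeFeatureNames}, \code{edgeFeatureNames}, \code{log}
#'   (per-epoch data.frame: epoch, train_mse, train_pairwise, val_total)
#'   and \code{bestEpoch}.
#' @export
trainModel <- function(trainData, valData, transformerCfg = transformerConfig(),
                       trainingCfg = trainingConfig(), verbose = FALSE) {
  trainTargets <- vapply(trainData, `[[`, "", "target")
  valTargets <- vapply(valData, `[[`, "", "target")
  if (length(intersect(trainTargets, valTargets)))
    stop("data hygiene violation: targets in both train and validation: ",
         paste(intersect(trainTargets, valTargets), collapse = ", "))
  flatten <- function(datasets) {
    out <- list()
    for (ds in datasets) {
      if (anyNA(ds$labels))
        stop("target without complete labels: ", ds$target)
      for (sub in ds$subgraphs) {
        sub$poolKey <- ds$target
        out[[length(out) + 1L]] <- sub
      }
    }
    out
  }
  trainSubs <- flatten(trainData)
  valSubs <- flatten(valData)
  labels <- setNames(lapply(trainData, `[[`, "labels"), trainTargets)
  labels[valTargets] <- lapply(valData, `[[`, "labels")

  ex <- trainSubs[[1L]]
  params <- initParameters(transformerCfg, ncol(ex$nodeFeatures),
                           ncol(ex$edgeFeatures))
  state <- .adamwInit(params)
  bestParams <- params
  bestVal <- Inf
  bestEpoch <- 0L
  badEpochs <- 0L
  log <- data.frame(epoch = integer(), train_mse = numeric(),
                    train_pairwise = numeric(), val_total = numeric())
  nTrain <- length(trainSubs)
  B <- min(trainingCfg$batchSize, nTrain)

  for (epoch in seq_len(trainingCfg$maxEpochs)) {
    set.seed(.deriveSeed(trainingCfg$seed, 500L + epoch))
    ord <- sample.int(nTrain)
    epochMse <- 0; epochPair <- 0
    nBatches <- ceiling(nTrain / B)
    for (bi in seq_len(nBatches)) {
      idx <- ord[((bi - 1L) * B + 1L):min(bi * B, nTrain)]
      gradSum <- NULL
      for (si in idx) {
        sub <- trainSubs[[si]]
        fw <- .forwardSubgraph(params, transformerCfg, sub, train = TRUE)
        y <- labels[[sub$poolKey]][sub$nodes]
        l1 <- mseLoss(y, fw$yhat)
        l2 <- if (length(y) >= 2L) pairwiseLoss(y, fw$yhat) else 0
        if (!is.finite(l1) || !is.finite(l2))
          stop("NaN/Inf loss at epoch ", epoch, ", subgraph ", si,
               " (target ", sub$poolKey, ")")
        epochMse <- epochMse + l1
        epochPair <- epochPair + l2
        dY <- .totalLossGrad(y, fw$yhat, trainingCfg$alpha,
                             trainingCfg$beta)
        g <- .backwardSubgraph(params, transformerCfg, sub, fw$cache, dY)
        gradSum <- if (is.null(gradSum)) g else
          .mapParams(`+`, gradSum, g)
      }
      grads <- .mapParams(function(x) x / length(idx), gradSum)
      if (trainingCfg$optimizer == "adamw") {
        upd <- .adamwStep(params, grads, state,
                          trainingCfg$learningRate,
                          trainingCfg$weightDecay)
        params <- upd$params
        state <- upd$state
      } else {
        params <- .sgdStep(params, grads, trainingCfg$learningRate,
                           trainingCfg$weightDecay)
      }
    }
    valLoss <- .evalSubgraphLoss(params, transformerCfg, valSubs, labels,
                                 trainingCfg$alpha, trainingCfg$beta)
    log <- rbind(log, data.frame(
      epoch = epoch, train_mse = epochMse / nTrain,
      train_pairwise = epochPair / nTrain, val_total = valLoss))
    if (verbose)
      message(sprintf(
        "epoch %d: train mse %.5f pairwise %.5f | val total %.5f",
        epoch, epochMse / nTrain, epochPair / nTrain, valLoss))
    if (valLoss < bestVal - 1e-9) {
      bestVal <- valLoss
      bestParams <- params
      bestEpoch <- epoch
      badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      if (badEpochs >= trainingCfg$patience) break
    }
  }

  list(version = "graphema-checkpoint-1",
       params = bestParams, config = transformerCfg,
       nodeFeatureNames = colnames(ex$nodeFeatures),
       edgeFeatureNames = colnames(ex$edgeFeatures),
       log = log, bestEpoch = bestEpoch, bestValLoss = bestVal,
       seed = trainingCfg$seed)
}
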