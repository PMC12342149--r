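#' Aggregation configuration
#'
#' @param method Per-decoy aggregation across subgraphs: \code{"mean"}
#'   (default, matches the averaging used for ensembling) or
#'   \code{"median"} (robust to outlier subgraphs).
#' @param nRepeats Independent sampling-plus-prediction repeats to average
#'   (default 5).
#' @return A validated list of class \code{"AggregationConfig"}.
#' @export
aggregationConfig <- function(method = c("mean", "median"), nRepeats = 5L) {
  method <- match.arg(method)
  .assertScalarNumber(nRepeats, "nRepeats", 1, Inf)
  structure(list(method = method, nRepeats = as.integer(nRepeats)),
            class = "AggregationConfig")
}

#' Aggregate per-subgraph predictions into final decoy scores
#'
#' Each decoy receives the mean (or median) of the predictions from all
#' subgraphs containing it, the sample standard deviation of those
#' predictions (0 when only one), and their count.
#'
#' @param perSubgraphScores Named list: decoy id to numeric vector of
#'   per-subgraph predictions.
#' @param method \code{"mean"} or \code{"median"}.
#' @param targetId Target identifier for the returned set.
#' @param decoyOrder Optional character vector fixing the output order
#'   (defaults to the list order).
#' @return A [PredictionSet-class].
#' @examples
#' aggregateSubgraphPredictions(
#'   list(d1 = c(0.5, 0.7, 0.9), d2 = 0.42), targetId = "T0001")
#' @export
aggregateSubgraphPredictions <- function(perSubgraphScores,
                                         method = c("mean", "median"),
                                         targetId = "target",
                                         decoyOrder = names(perSubgraphScores)) {
  method <- match.arg(method)
  if (!length(perSubgraphScores)) stop("no predictions to aggregate")
  missing <- setdiff(decoyOrder, names(perSubgraphScores))
  if (length(missing))
    stop("decoys with no subgraph predictions: ",
         paste(missing, collapse = ", "))
  agg <- if (method == "mean") mean else median
  scores <- vapply(decoyOrder, function(id) agg(perSubgraphScores[[id]]),
                   0)
  stds <- vapply(decoyOrder, function(id) {
    v <- perSubgraphScores[[id]]
    if (length(v) > 1L) sd(v) else 0
  }, 0)
  ns <- vapply(decoyOrder, function(id)
    length(perSubgraphScores[[id]]), 0L)
  PredictionSet(targetId, decoyOrder, scores, stds, ns)
}

#' Predict decoy quality for one pool with one checkpoint
#'
#' Samples subgraphs, runs the graph transformer on each in evaluation
#' mode, and aggregates the per-subgraph node predictions into one score
#' per decoy.
#'
#' @param graph A [ModelGraph-class] built with the checkpoint's feature
#'   variant.
#' @param tm,qs The pool's TM and QS [PairwiseMatrix-class] objects.
#' @param checkpoint A trained checkpoint.
#' @param samplerCfg A [samplerConfig()]; its seed drives the sampling.
#' @param method Aggregation method, \code{"mean"} or \code{"median"}.
#' @param targetId Target identifier for the returned set.
#' @return A [PredictionSet-class].
#' @export
predictPool <- function(graph, tm, qs, checkpoint,
                        samplerCfg = samplerConfig(),
                        method = c("mean", "median"),
                        targetId = "target") {
  method <- match.arg(method)
  sam <- sampleSubgraphs(graph, tm, qs, samplerCfg)
  perDecoy <- rep(list(numeric()), length(graph@ids))
  names(perDecoy) <- graph@ids
  for (sub in sam$subgraphs) {
    yhat <- predictSubgraph(checkpoint, sub)
    for (a in seq_along(sub$ids)) {
      id <- sub$ids[a]
      perDecoy[[id]] <- c(perDecoy[[id]], yhat[[a]])
    }
  }
  aggregateSubgraphPredictions(perDecoy, method, targetId,
                               decoyOrder = graph@ids)
}

#' Repeat sampling and prediction, then average
#'
#' Runs [predictPool()] \code{nRepeats} times with distinct derived seeds
#' and averages the per-decoy scores; the reported dispersion is the
#' across-repeat standard deviation, quantifying the sampling randomness
#' of a single run.
#'
#' @inheritParams predictPool
#' @param nRepeats Number of repeats (default 5).
#' @return A [PredictionSet-class]; \code{nSubgraphs} is the total number
#'   of contributing subgraph predictions across repeats.
#' @export
repeatAndAverage <- function(graph, tm, qs, checkpoint,
                             samplerCfg = samplerConfig(),
                             nRepeats = 5L, method = c("mean", "median"),
                             targetId = "target") {
  method <- match.arg(method)
  .assertScalarNumber(nRepeats, "nRepeats", 1, Inf)
  runs <- lapply(seq_len(nRepeats), function(r) {
    cfg <- samplerCfg
    # the first repeat reproduces a single run; later repeats resample
    if (r > 1L) cfg$seed <- .deriveSeed(samplerCfg$seed, 600L + r)
    predictPool(graph, tm, qs, checkpoint, cfg, method, targetId)
  })
  mat <- vapply(runs, function(ps) ps@scores, numeric(length(graph@ids)))
  mat <- matrix(mat, nrow = length(graph@ids))
  counts <- vapply(runs, function(ps) ps@nSubgraphs,
                   integer(length(graph@ids)))
  counts <- matrix(counts, nrow = length(graph@ids))
  PredictionSet(targetId, graph@ids, rowMeans(mat),
                if (nRepeats > 1L) apply(mat, 1L, sd) else
                  rep(0, length(graph@ids)),
                as.integer(rowSums(counts)))
}

#' Ensemble predictions across checkpoints
#'
#' Unweighted per-decoy mean of the member [PredictionSet-class] scores
#' (e.g. the cross-validation models of several feature variants).
#'
#' @param predictions List of [PredictionSet-class] objects over the same
#'   decoys.
#' @return A [PredictionSet-class]; \code{std} is the across-member
#'   standard deviation.
#' @export
ensemblePredictions <- function(predictions) {
  if (!length(predictions)) stop("empty checkpoint/prediction list")
  ids <- predictions[[1L]]@decoyIds
  for (ps in predictions)
    if (!identical(sort(ps@decoyIds), sort(ids)))
      stop("ensemble members cover different decoys")
  mat <- vapply(predictions, function(ps)
    ps@scores[match(ids, ps@decoyIds)], numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  counts <- matrix(vapply(predictions, function(ps)
    ps@nSubgraphs[match(ids, ps@decoyIds)], integer(length(ids))),
    nrow = length(ids))
  PredictionSet(predictions[[1L]]@targetId, ids, rowMeans(mat),
                if (ncol(mat) > 1L) apply(mat, 1L, sd) else
                  rep(0, length(ids)),
                as.integer(rowSums(counts)))
}
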