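#' @import methods
#' @importFrom stats cor kmeans median quantile rnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

.PAIRWISE_METRICS <- c("tm", "qs", "cad", "dockq_ave", "dockq_wave",
                       "common_interfaces")
.BOUNDED_METRICS <- c("tm", "qs", "cad", "dockq_ave", "dockq_wave")
.SCORE_NAMES <- c("icps", "enqa", "dproqa", "voroif_gnn", "gcpnet_ema",
                  "plddt", "custom")

#' Decoy pool for one target
#'
#' A \code{DecoyPool} holds the decoys (predicted structural models) of one
#' protein complex target: their identifiers, the number of residues resolved
#' in each decoy, the target (native) sequence length, and optionally the
#' per-decoy true TM-score labels used for training and evaluation.
#'
#' @slot targetId Single target identifier (e.g. \code{"H1215"}).
#' @slot nativeLength Positive integer, residues of the target sequence.
#' @slot decoyIds Character vector of unique decoy identifiers (pool order).
#' @slot lengths Integer vector of per-decoy resolved lengths.
#' @slot trueTM Numeric vector of true TM-scores in [0, 1], \code{NA} when
#'   unlabeled.
#'
#' @seealso [DecoyPool()] for the constructor.
#' @export
setClass("DecoyPool",
  representation(
    targetId = "character",
    nativeLength = "integer",
    decoyIds = "character",
    lengths = "integer",
    trueTM = "numeric"
  )
)

setValidity("DecoyPool", function(object) {
  msg <- character()
  n <- length(object@decoyIds)
  if (length(object@targetId) != 1L || !nzchar(object@targetId))
    msg <- c(msg, "targetId must be a single non-empty string")
  if (length(object@nativeLength) != 1L || is.na(object@nativeLength) ||
      object@nativeLength < 1L)
    msg <- c(msg, "nativeLength must be a positive integer")
  if (n < 2L)
    msg <- c(msg, "a pool needs at least 2 decoys")
  if (anyDuplicated(object@decoyIds))
    msg <- c(msg, "decoy ids must be unique within a target")
  if (length(object@lengths) != n)
    msg <- c(msg, "lengths must align with decoyIds")
  else if (any(is.na(object@lengths)) || any(object@lengths < 1L))
    msg <- c(msg, "decoy lengths must be positive integers")
  if (length(object@trueTM) != n)
    msg <- c(msg, "trueTM must align with decoyIds")
  else {
    lab <- object@trueTM[!is.na(object@trueTM)]
    if (length(lab) && (any(lab < 0) || any(lab > 1)))
      msg <- c(msg, "trueTM labels must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DecoyPool
#'
#' @param targetId Target identifier.
#' @param nativeLength Residues of the target sequence (positive integer).
#' @param decoyIds Unique decoy identifiers, in pool order.
#' @param lengths Per-decoy resolved lengths; defaults to \code{nativeLength}
#'   for every decoy (full-length models).
#' @param trueTM Optional true TM-score labels in [0, 1]; \code{NA} = unknown.
#' @return A [DecoyPool-class] object.
#' @examples
#' pool <- DecoyPool("T0001", 120L, c("d1", "d2", "d3"),
#'                   trueTM = c(0.9, 0.5, NA))
#' decoyIds(pool)
#' @export
DecoyPool <- function(targetId, nativeLength, decoyIds,
                      lengths = rep(as.integer(nativeLength),
                                    length(decoyIds)),
                      trueTM = rep(NA_real_, length(decoyIds))) {
  new("DecoyPool",
      targetId = as.character(targetId),
      nativeLength = as.integer(nativeLength),
      decoyIds = as.character(decoyIds),
      lengths = as.integer(lengths),
      trueTM = as.numeric(trueTM))
}

#' Pairwise similarity matrix over a decoy pool
#'
#' Square symmetric matrix of a pairwise structural-similarity metric
#' (TM-score, QS-score, CAD-score, DockQ averages, or the integer count of
#' common interaction interfaces) over the decoys of one target.
#'
#' Bounded metrics (\code{tm}, \code{qs}, \code{cad}, \code{dockq_ave},
#' \code{dockq_wave}) must lie in [0, 1] with unit diagonal;
#' \code{common_interfaces} holds non-negative integers and its diagonal is
#' ignored.
#'
#' @slot metricName One of \code{"tm"}, \code{"qs"}, \code{"cad"},
#'   \code{"dockq_ave"}, \code{"dockq_wave"}, \code{"common_interfaces"}.
#' @slot ids Decoy identifiers (row/column order).
#' @slot values Numeric matrix, symmetric within 1e-9.
#'
#' @seealso [PairwiseMatrix()], [readPairwiseMatrix()]
#' @export
setClass("PairwiseMatrix",
  representation(
    metricName = "character",
    ids = "character",
    values = "matrix"
  )
)

setValidity("PairwiseMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  v <- object@values
  if (length(object@metricName) != 1L ||
      !(object@metricName %in% .PAIRWISE_METRICS))
    msg <- c(msg, sprintf("metricName must be one of: %s",
                          paste(.PAIRWISE_METRICS, collapse = ", ")))
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "values must be an n x n numeric matrix over ids")
  else {
    if (anyNA(v))
      msg <- c(msg, "values must not contain NA")
    else {
      if (max(abs(v - t(v))) > 1e-9)
        msg <- c(msg, "values must be symmetric within 1e-9")
      if (object@metricName %in% .BOUNDED_METRICS) {
        if (any(v < -1e-12) || any(v > 1 + 1e-12))
          msg <- c(msg, sprintf("%s similarities must lie in [0, 1]",
                                object@metricName))
        if (n > 0 && max(abs(diag(v) - 1)) > 1e-9)
          msg <- c(msg, "diagonal must equal the self-similarity 1.0")
      } else if (object@metricName == "common_interfaces") {
        off <- v[row(v) != col(v)]
        if (length(off) && (any(off < 0) ||
                            max(abs(off - round(off))) > 1e-9))
          msg <- c(msg, "common_interfaces must be non-negative integers")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PairwiseMatrix
#'
#' Asymmetric input (e.g. TM-scores normalized by either structure) is
#' symmetrized as \eqn{(M + M^T)/2}; a warning is emitted when any pair
#' disagrees by more than \code{warnAsym} before symmetrization.
#'
#' @param metricName Metric name; see [PairwiseMatrix-class].
#' @param ids Decoy identifiers.
#' @param values Square numeric matrix aligned to \code{ids}.
#' @param warnAsym Asymmetry tolerance that triggers a warning (default 0.05).
#' @return A [PairwiseMatrix-class] object.
#' @examples
#' m <- matrix(c(1, .7, .7, 1), 2, dimnames = list(c("a","b"), c("a","b")))
#' PairwiseMatrix("tm", c("a", "b"), m)
#' @export
PairwiseMatrix <- function(metricName, ids, values, warnAsym = 0.05) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop("non-square pairwise matrix: ", nrow(values), " x ", ncol(values))
  if (anyNA(values))
    stop("pairwise matrix contains NA cells")
  asym <- max(abs(values - t(values)))
  if (asym > warnAsym)
    warning(sprintf(
      "pairwise %s matrix asymmetric by up to %.4f; symmetrizing by the mean",
      metricName, asym))
  values <- (values + t(values)) / 2
  if (metricName == "common_interfaces")
    diag(values) <- 0
  ids <- as.character(ids)
  dimnames(values) <- list(ids, ids)
  new("PairwiseMatrix", metricName = as.character(metricName),
      ids = ids, values = values)
}

#' Single-model quality score table
#'
#' Raw per-decoy scores from one single-model accuracy estimator (e.g.
#' ICPS, EnQA, DProQA, VoroIF-GNN, GCPNet-EMA, AlphaFold pLDDT). Missing
#' decoys are carried as \code{NA} and imputed downstream with an explicit
#' missingness mask.
#'
#' @slot scoreName One of \code{"icps"}, \code{"enqa"}, \code{"dproqa"},
#'   \code{"voroif_gnn"}, \code{"gcpnet_ema"}, \code{"plddt"},
#'   \code{"custom"}.
#' @slot scores Named numeric vector, decoy id to raw score (\code{NA} =
#'   missing).
#' @seealso [ScoreTable()], [readScoreTable()]
#' @export
setClass("ScoreTable",
  representation(
    scoreName = "character",
    scores = "numeric"
  )
)

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (length(object@scoreName) != 1L ||
      !(object@scoreName %in% .SCORE_NAMES))
    msg <- c(msg, sprintf("scoreName must be one of: %s",
                          paste(.SCORE_NAMES, collapse = ", ")))
  if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
    msg <- c(msg, "scores must be named by unique decoy ids")
  fin <- object@scores[!is.na(object@scores)]
  if (length(fin) && any(!is.finite(fin)))
    msg <- c(msg, "raw scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreTable
#'
#' @param scoreName Score name; see [ScoreTable-class].
#' @param scores Named numeric vector (decoy id to raw score).
#' @return A [ScoreTable-class] object.
#' @examples
#' ScoreTable("enqa", c(d1 = 0.9, d2 = 0.5))
#' @export
ScoreTable <- function(scoreName, scores) {
  s <- as.numeric(scores)
  names(s) <- names(scores)
  new("ScoreTable", scoreName = as.character(scoreName), scores = s)
}

#' Pairwise-similarity model graph
#'
#' The full similarity graph of one decoy pool: nodes are decoys, an
#' undirected edge joins two decoys whose pairwise TM-score exceeds the edge
#' threshold, node features hold consensus (mean pairwise similarity) and
#' length-normalized single-model scores, and edge features hold the scaled
#' common-interface count plus pairwise similarity metrics.
#'
#' @slot ids Decoy identifiers (node order).
#' @slot adjacency n x n logical matrix, symmetric, no self loops.
#' @slot nodeFeatures n x F numeric matrix, rows ordered as \code{ids},
#'   named columns.
#' @slot edgeIndex m x 2 integer matrix of undirected edges (i < j).
#' @slot edgeFeatures m x Fe numeric matrix with named columns.
#' @slot edgeThreshold TM-score above which an edge is created.
#' @slot variant Feature variant: \code{"basic"}, \code{"gcp"} or
#'   \code{"advanced"}.
#' @seealso [buildModelGraph()]
#' @export
setClass("ModelGraph",
  representation(
    ids = "character",
    adjacency = "matrix",
    nodeFeatures = "matrix",
    edgeIndex = "matrix",
    edgeFeatures = "matrix",
    edgeThreshold = "numeric",
    variant = "character"
  )
)

setValidity("ModelGraph", function(object) {
  msg <- character()
  n <- length(object@ids)
  A <- object@adjacency
  if (!is.logical(A) || nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency must be an n x n logical matrix")
  else {
    if (any(diag(A)))
      msg <- c(msg, "no self-loops allowed")
    if (!identical(A, t(A)))
      msg <- c(msg, "adjacency must be symmetric")
  }
  if (nrow(object@nodeFeatures) != n)
    msg <- c(msg, "nodeFeatures rows must align with ids")
  if (anyNA(object@nodeFeatures) || any(!is.finite(object@nodeFeatures)))
    msg <- c(msg, "node features must be finite")
  m <- nrow(object@edgeIndex)
  if (m > 0) {
    if (any(object@edgeIndex[, 1] >= object@edgeIndex[, 2]))
      msg <- c(msg, "edgeIndex must store undirected edges with i < j")
    if (nrow(object@edgeFeatures) != m)
      msg <- c(msg, "edgeFeatures rows must align with edgeIndex")
    if (anyNA(object@edgeFeatures) || any(!is.finite(object@edgeFeatures)))
      msg <- c(msg, "edge features must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Per-decoy predicted quality scores
#'
#' Final aggregated quality predictions for one target: per decoy the
#' aggregated score in [0, 1], the dispersion of the per-subgraph (or
#' per-repeat) predictions it was aggregated from, and how many subgraph
#' predictions contributed.
#'
#' @slot targetId Target identifier.
#' @slot decoyIds Decoy identifiers (pool order).
#' @slot scores Aggregated predicted quality per decoy, in [0, 1].
#' @slot std Non-negative dispersion per decoy (0 when a single prediction).
#' @slot nSubgraphs Integer count of contributing predictions per decoy.
#' @seealso [PredictionSet()], [writePredictions()]
#' @export
setClass("PredictionSet",
  representation(
    targetId = "character",
    decoyIds = "character",
    scores = "numeric",
    std = "numeric",
    nSubgraphs = "integer"
  )
)

setValidity("PredictionSet", function(object) {
  msg <- character()
  n <- length(object@decoyIds)
  if (n < 1L)
    msg <- c(msg, "a PredictionSet must cover at least one decoy")
  if (anyDuplicated(object@decoyIds))
    msg <- c(msg, "decoy ids must be unique")
  if (length(object@scores) != n || length(object@std) != n ||
      length(object@nSubgraphs) != n)
    msg <- c(msg, "scores, std and nSubgraphs must align with decoyIds")
  else {
    if (anyNA(object@scores) || any(object@scores < -1e-9) ||
        any(object@scores > 1 + 1e-9))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (anyNA(object@std) || any(object@std < 0))
      msg <- c(msg, "std must be non-negative")
    if (anyNA(object@nSubgraphs) || any(object@nSubgraphs < 1L))
      msg <- c(msg, "every decoy needs at least one contributing prediction")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param targetId Target identifier.
#' @param decoyIds Decoy identifiers.
#' @param scores Aggregated predicted quality scores in [0, 1].
#' @param std Per-decoy dispersion (defaults to 0).
#' @param nSubgraphs Contributing prediction counts (defaults to 1).
#' @return A [PredictionSet-class] object.
#' @examples
#' PredictionSet("T0001", c("d1", "d2"), c(0.8, 0.3))
#' @export
PredictionSet <- function(targetId, decoyIds, scores,
                          std = rep(0, length(decoyIds)),
                          nSubgraphs = rep(1L, length(decoyIds))) {
  new("PredictionSet", targetId = as.character(targetId),
      decoyIds = as.character(decoyIds), scores = as.numeric(scores),
      std = as.numeric(std), nSubgraphs = as.integer(nSubgraphs))
}
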