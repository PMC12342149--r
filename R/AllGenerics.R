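#' Accessors for GraphEMA classes
#'
#' Small accessor family: \code{decoyIds()} returns the decoy identifiers of
#' a pool, matrix, graph or prediction set; \code{trueTM()} the labels of a
#' pool; \code{metricName()} / \code{similarityValues()} the metric and value
#' matrix of a [PairwiseMatrix-class]; \code{predScores()}, \code{predStd()}
#' and \code{nSubgraphs()} the components of a [PredictionSet-class];
#' \code{nodeFeatures()}, \code{edgeFeatures()}, \code{edgeIndex()} and
#' \code{adjacencyMatrix()} the components of a [ModelGraph-class].
#'
#' @param x Object.
#' @return The corresponding slot value.
#' @examples
#' pool <- DecoyPool("T0001", 100L, c("d1", "d2"), trueTM = c(0.8, 0.4))
#' decoyIds(pool)
#' trueTM(pool)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("decoyIds", function(x) standardGeneric("decoyIds"))
#' @rdname accessors
#' @export
setGeneric("trueTM", function(x) standardGeneric("trueTM"))
#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("predScores", function(x) standardGeneric("predScores"))
#' @rdname accessors
#' @export
setGeneric("predStd", function(x) standardGeneric("predStd"))
#' @rdname accessors
#' @export
setGeneric("nSubgraphs", function(x) standardGeneric("nSubgraphs"))
#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname accessors
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))
#' @rdname accessors
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setMethod("decoyIds", "DecoyPool", function(x) x@decoyIds)
#' @rdname accessors
#' @export
setMethod("decoyIds", "PairwiseMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("decoyIds", "ModelGraph", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("decoyIds", "PredictionSet", function(x) x@decoyIds)
#' @rdname accessors
#' @export
setMethod("trueTM", "DecoyPool", function(x)
  setNames(x@trueTM, x@decoyIds))
#' @rdname accessors
#' @export
setMethod("metricName", "PairwiseMatrix", function(x) x@metricName)
#' @rdname accessors
#' @export
setMethod("metricName", "ScoreTable", function(x) x@scoreName)
#' @rdname accessors
#' @export
setMethod("similarityValues", "PairwiseMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("predScores", "PredictionSet", function(x)
  setNames(x@scores, x@decoyIds))
#' @rdname accessors
#' @export
setMethod("predStd", "PredictionSet", function(x)
  setNames(x@std, x@decoyIds))
#' @rdname accessors
#' @export
setMethod("nSubgraphs", "PredictionSet", function(x)
  setNames(x@nSubgraphs, x@decoyIds))
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "ModelGraph", function(x) x@nodeFeatures)
#' @rdname accessors
#' @export
setMethod("edgeFeatures", "ModelGraph", function(x) x@edgeFeatures)
#' @rdname accessors
#' @export
setMethod("edgeIndex", "ModelGraph", function(x) x@edgeIndex)
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "ModelGraph", function(x) x@adjacency)

setMethod("show", "DecoyPool", function(object) {
  nlab <- sum(!is.na(object@trueTM))
  cat(sprintf(
    "DecoyPool '%s': %d decoys, native length %d, %d labeled\n",
    object@targetId, length(object@decoyIds), object@nativeLength, nlab))
})

setMethod("show", "PairwiseMatrix", function(object) {
  n <- length(object@ids)
  off <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("PairwiseMatrix '%s': %d x %d", object@metricName, n, n))
  if (length(off))
    cat(sprintf(", off-diagonal mean %.3f", mean(off)))
  cat("\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable '%s': %d decoys (%d missing)\n",
              object@scoreName, length(object@scores),
              sum(is.na(object@scores))))
})

setMethod("show", "ModelGraph", function(object) {
  cat(sprintf(
    "ModelGraph (%s): %d nodes, %d edges (TM > %.2f), %d node / %d edge features\n",
    object@variant, length(object@ids), nrow(object@edgeIndex),
    object@edgeThreshold, ncol(object@nodeFeatures),
    ncol(object@edgeFeatures)))
})

setMethod("show", "PredictionSet", function(object) {
  top <- which.max(object@scores)
  cat(sprintf(
    "PredictionSet '%s': %d decoys, top-1 %s (%.4f), median n_subgraphs %d\n",
    object@targetId, length(object@decoyIds), object@decoyIds[top],
    object@scores[top], as.integer(stats::median(object@nSubgraphs))))
})
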