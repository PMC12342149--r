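#' Feature variant specification
#'
#' The three feature variants differ only in which features enter the graph:
#' \describe{
#'   \item{basic}{Node: full-graph and subgraph-level mean pairwise TM-score
#'     and QS-score, plus length-normalized single-model scores (ICPS, EnQA,
#'     DProQA, VoroIF-GNN) each with a 0/1 missingness mask. Edge: scaled
#'     common-interface count, TM-score, QS-score.}
#'   \item{gcp}{Basic plus the GCPNet-EMA single-model score (and mask).}
#'   \item{advanced}{GCP plus per-decoy mean pairwise DockQ_ave, DockQ_wave
#'     and CAD-score node features, and the corresponding per-edge pairwise
#'     interface metrics.}
#' }
#'
#' @param variant \code{"basic"}, \code{"gcp"} or \code{"advanced"}.
#' @return A list with \code{variant}, \code{nodeFeatureNames},
#'   \code{edgeFeatureNames}, \code{singleScores} (required score tables)
#'   and \code{extraMetrics} (required pairwise matrices beyond tm/qs).
#' @examples
#' featureSpec("basic")$nodeFeatureNames
#' @export
featureSpec <- function(variant = c("basic", "gcp", "advanced")) {
  variant <- match.arg(variant)
  single <- c("icps", "enqa", "dproqa", "voroif_gnn")
  if (variant %in% c("gcp", "advanced"))
    single <- c(single, "gcpnet_ema")
  consensus <- c("graph_mean_tm", "graph_mean_qs",
                 "subgraph_mean_tm", "subgraph_mean_qs")
  extraMetrics <- character()
  nodeExtra <- character()
  edgeExtra <- character()
  if (variant == "advanced") {
    extraMetrics <- c("dockq_ave", "dockq_wave", "cad")
    nodeExtra <- paste0("graph_mean_", extraMetrics)
    edgeExtra <- extraMetrics
  }
  list(
    variant = variant,
    nodeFeatureNames = c(consensus, single, paste0(single, "_missing"),
                         nodeExtra),
    edgeFeatureNames = c("common_interfaces", "tm", "qs", edgeExtra),
    singleScores = single,
    extraMetrics = extraMetrics)
}

#' Build the edge set of a similarity graph
#'
#' An undirected edge joins decoys \eqn{i \ne j} iff their pairwise TM-score
#' strictly exceeds \code{threshold} (default 0.5, the same-fold cutoff).
#'
#' @param tm A [PairwiseMatrix-class] with metric \code{"tm"}.
#' @param threshold Edge threshold in [0, 1].
#' @return m x 2 integer matrix of undirected edges (row indices, i < j).
#' @examples
#' m <- matrix(c(1, .6, .4, .6, 1, .7, .4, .7, 1), 3,
#'             dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
#' buildEdges(PairwiseMatrix("tm", paste0("d", 1:3), m))
#' @export
buildEdges <- function(tm, threshold = 0.5) {
  stopifnot(is(tm, "PairwiseMatrix"))
  .assertScalarNumber(threshold, "threshold", 0, 1)
  v <- tm@values
  n <- nrow(v)
  sel <- which(upper.tri(v) & v > threshold, arr.ind = TRUE)
  e <- matrix(as.integer(sel), ncol = 2L,
              dimnames = list(NULL, c("i", "j")))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Length-normalize a single-model quality score
#'
#' Multiplies the raw score by the ratio of the decoy length to the native
#' (target) length, penalizing incomplete models; bounded scores are then
#' clipped back to [0, 1].
#'
#' @param raw Raw score (vectorized).
#' @param decoyLength Residues resolved in the decoy.
#' @param nativeLength Residues of the target sequence.
#' @param bounded Clip the result to [0, 1] (default TRUE; raw bounded
#'   scores can exceed 1 after scaling when a decoy is longer than the
#'   native sequence).
#' @return Normalized score(s).
#' @examples
#' normalizeSingleModelScore(0.8, 100, 200)  # 0.4
#' @export
normalizeSingleModelScore <- function(raw, decoyLength, nativeLength,
                                      bounded = TRUE) {
  if (any(nativeLength <= 0))
    stop("nativeLength must be positive")
  if (any(decoyLength <= 0))
    stop("decoyLength must be positive")
  out <- raw * decoyLength / nativeLength
  if (bounded) out <- .clip01(out)
  out
}

.requireMatrix <- function(matrices, metric) {
  if (is.null(matrices[[metric]]))
    stop("required pairwise matrix missing: ", metric)
  m <- matrices[[metric]]
  stopifnot(is(m, "PairwiseMatrix"))
  m
}

.alignMatrix <- function(m, ids) {
  if (!all(ids %in% m@ids))
    stop("pairwise ", m@metricName, " matrix missing decoys: ",
         paste(setdiff(ids, m@ids), collapse = ", "))
  m@values[ids, ids, drop = FALSE]
}

#' Compute node features
#'
#' Per decoy: full-graph mean pairwise TM-score and QS-score (self
#' excluded), placeholders for the subgraph-level means (initialized to the
#' full-graph values and recomputed per sampled subgraph), length-normalized
#' single-model scores per the feature variant, one 0/1 missingness mask per
#' single-model score, and (variant \code{advanced}) full-graph mean
#' pairwise interface metrics. Missing single-model scores are imputed with
#' the pool median of that score (0.5 when a scorer produced nothing at
#' all) and flagged in the mask.
#'
#' @param pool A [DecoyPool-class].
#' @param matrices Named list of [PairwiseMatrix-class] (needs \code{tm} and
#'   \code{qs}; \code{advanced} additionally \code{dockq_ave},
#'   \code{dockq_wave}, \code{cad}).
#' @param scoreTables Named list of [ScoreTable-class].
#' @param spec A [featureSpec()] list.
#' @return n x F numeric matrix with named columns, rows in pool order.
#' @export
computeNodeFeatures <- function(pool, matrices, scoreTables,
                                spec = featureSpec("basic")) {
  ids <- pool@decoyIds
  n <- length(ids)
  tm <- .alignMatrix(.requireMatrix(matrices, "tm"), ids)
  qs <- .alignMatrix(.requireMatrix(matrices, "qs"), ids)
  meanTM <- .rowMeanOffDiagonal(tm)
  meanQS <- .rowMeanOffDiagonal(qs)
  X <- cbind(graph_mean_tm = meanTM, graph_mean_qs = meanQS,
             subgraph_mean_tm = meanTM, subgraph_mean_qs = meanQS)
  for (sn in spec$singleScores) {
    tab <- scoreTables[[sn]]
    raw <- rep(NA_real_, n)
    if (!is.null(tab)) {
      stopifnot(is(tab, "ScoreTable"))
      raw <- unname(tab@scores[ids])
    }
    missing <- is.na(raw)
    norm <- rep(NA_real_, n)
    norm[!missing] <- normalizeSingleModelScore(
      raw[!missing], pool@lengths[!missing], pool@nativeLength)
    fill <- if (all(missing)) 0.5 else median(norm, na.rm = TRUE)
    norm[missing] <- fill
    X <- cbind(X, norm)
    colnames(X)[ncol(X)] <- sn
    X <- cbind(X, as.numeric(missing))
    colnames(X)[ncol(X)] <- paste0(sn, "_missing")
  }
  for (metric in spec$extraMetrics) {
    vals <- .alignMatrix(.requireMatrix(matrices, metric), ids)
    X <- cbind(X, .rowMeanOffDiagonal(vals))
    colnames(X)[ncol(X)] <- paste0("graph_mean_", metric)
  }
  X <- X[, spec$nodeFeatureNames, drop = FALSE]
  rownames(X) <- ids
  X
}

#' Compute edge features
#'
#' Per undirected edge (i, j): the number of common interaction interfaces
#' scaled to [0, 1] by a configurable cap, the pairwise TM-score and
#' QS-score, plus (variant \code{advanced}) the pairwise DockQ_ave,
#' DockQ_wave and CAD-score.
#'
#' @param edges m x 2 integer edge matrix from [buildEdges()].
#' @param ids Decoy identifiers the edge indices refer to.
#' @param matrices Named list of [PairwiseMatrix-class].
#' @param spec A [featureSpec()] list.
#' @param interfaceCap Common-interface count mapped to feature value 1;
#'   larger counts are clipped (default 10).
#' @return m x Fe numeric matrix with named columns.
#' @export
computeEdgeFeatures <- function(edges, ids, matrices,
                                spec = featureSpec("basic"),
                                interfaceCap = 10) {
  .assertScalarNumber(interfaceCap, "interfaceCap", 1, Inf)
  m <- nrow(edges)
  tm <- .alignMatrix(.requireMatrix(matrices, "tm"), ids)
  qs <- .alignMatrix(.requireMatrix(matrices, "qs"), ids)
  ci <- matrices[["common_interfaces"]]
  civ <- if (is.null(ci)) matrix(0, length(ids), length(ids))
         else .alignMatrix(ci, ids)
  idx <- edges
  E <- cbind(
    common_interfaces = pmin(civ[idx], interfaceCap) / interfaceCap,
    tm = tm[idx],
    qs = qs[idx])
  for (metric in spec$extraMetrics) {
    vals <- .alignMatrix(.requireMatrix(matrices, metric), ids)
    E <- cbind(E, vals[idx])
    colnames(E)[ncol(E)] <- metric
  }
  E <- E[, spec$edgeFeatureNames, drop = FALSE]
  if (m == 0L) E <- E[0L, , drop = FALSE]
  E
}

#' Build the full pairwise-similarity model graph
#'
#' Assembles the [ModelGraph-class] for a decoy pool: the edge set
#' (pairwise TM-score strictly above \code{edgeThreshold}), node features
#' and edge features for the requested feature variant. Isolated decoys
#' (no similar neighbor) stay in the graph; during attention their
#' neighborhood degenerates to self only.
#'
#' @param pool A [DecoyPool-class].
#' @param matrices Named list of [PairwiseMatrix-class].
#' @param scoreTables Named list of [ScoreTable-class].
#' @param spec A [featureSpec()] list.
#' @param edgeThreshold TM-score edge cutoff (default 0.5).
#' @param interfaceCap Scaling cap for common-interface counts (default 10).
#' @return A [ModelGraph-class].
#' @export
buildModelGraph <- function(pool, matrices, scoreTables = list(),
                            spec = featureSpec("basic"),
                            edgeThreshold = 0.5, interfaceCap = 10) {
  stopifnot(is(pool, "DecoyPool"))
  ids <- pool@decoyIds
  n <- length(ids)
  tm <- .requireMatrix(matrices, "tm")
  edges <- buildEdges(
    PairwiseMatrix("tm", ids, .alignMatrix(tm, ids)), edgeThreshold)
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  X <- computeNodeFeatures(pool, matrices, scoreTables, spec)
  E <- computeEdgeFeatures(edges, ids, matrices, spec, interfaceCap)
  new("ModelGraph", ids = ids, adjacency = A, nodeFeatures = X,
      edgeIndex = edges, edgeFeatures = E,
      edgeThreshold = edgeThreshold, variant = spec$variant)
}
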