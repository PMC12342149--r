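#' Sampler configuration
#'
#' Controls structural-similarity-based subgraph sampling: the subgraph node
#' cap, the number of subgraphs, the average-similarity threshold that
#' switches between cluster-balanced and uniform sampling, and the K-means /
#' silhouette cluster-number search range.
#'
#' @param maxNodes Maximum nodes per subgraph (default 50).
#' @param nSubgraphs Number of subgraphs to sample (default 2000).
#' @param pssModeThreshold Average pairwise TM-score at or above which the
#'   pool counts as an easy case and subgraphs are drawn uniformly without
#'   clustering (default 0.8).
#' @param kMin,kMax Cluster-number search range for K-means (defaults 2, 10).
#' @param nStart K-means restarts (default 10).
#' @param seed Integer seed driving all sampling randomness.
#' @return A validated list of class \code{"SamplerConfig"}.
#' @export
samplerConfig <- function(maxNodes = 50L, nSubgraphs = 2000L,
                          pssModeThreshold = 0.8, kMin = 2L, kMax = 10L,
                          nStart = 10L, seed = 1L) {
  .assertScalarNumber(maxNodes, "maxNodes", 2, Inf)
  .assertScalarNumber(nSubgraphs, "nSubgraphs", 1, Inf)
  .assertScalarNumber(pssModeThreshold, "pssModeThreshold", 0, 1)
  .assertScalarNumber(kMin, "kMin", 2, Inf)
  .assertScalarNumber(kMax, "kMax", kMin, Inf)
  structure(list(maxNodes = as.integer(maxNodes),
                 nSubgraphs = as.integer(nSubgraphs),
                 pssModeThreshold = pssModeThreshold,
                 kMin = as.integer(kMin), kMax = as.integer(kMax),
                 nStart = as.integer(nStart), seed = as.integer(seed)),
            class = "SamplerConfig")
}

#' Average pairwise similarity of a pool
#'
#' Mean pairwise TM-score over all unordered off-diagonal decoy pairs; the
#' quantity that decides between cluster-balanced and uniform subgraph
#' sampling.
#'
#' @param tm A [PairwiseMatrix-class] (metric \code{tm}).
#' @return Scalar average pairwise similarity.
#' @examples
#' m <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3,
#'             dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
#' averagePSS(PairwiseMatrix("tm", paste0("d", 1:3), m))  # 0.4
#' @export
averagePSS <- function(tm) {
  stopifnot(is(tm, "PairwiseMatrix"))
  v <- tm@values
  n <- nrow(v)
  if (n < 2L) stop("average PSS needs at least 2 decoys")
  mean(v[upper.tri(v)])
}

#' Choose the number of structural clusters by silhouette
#'
#' Each decoy is represented by its row of pairwise similarity scores
#' against the whole pool; K-means is fitted for each k in
#' [\code{kMin}, min(\code{kMax}, n - 1)] and the k with the highest mean
#' silhouette width (Euclidean distance on similarity rows) is returned.
#' Silhouette ties break toward the smaller k.
#'
#' @param tm A [PairwiseMatrix-class].
#' @param config A [samplerConfig()].
#' @return A list with \code{k} (chosen number of clusters),
#'   \code{cluster} (integer assignment per decoy) and
#'   \code{silhouette} (named vector of mean widths per candidate k).
#' @export
chooseKSilhouette <- function(tm, config = samplerConfig()) {
  stopifnot(is(tm, "PairwiseMatrix"))
  v <- tm@values
  n <- nrow(v)
  kHi <- min(config$kMax, n - 1L)
  if (kHi < config$kMin)
    stop("too few decoys (", n, ") to form ", config$kMin, " clusters")
  d <- stats::dist(v)
  ks <- seq.int(config$kMin, kHi)
  sil <- rep(NA_real_, length(ks))
  fits <- vector("list", length(ks))
  set.seed(.deriveSeed(config$seed, 101L))
  for (a in seq_along(ks)) {
    fit <- suppressWarnings(
      kmeans(v, centers = ks[a], nstart = config$nStart, iter.max = 50L))
    fits[[a]] <- fit$cluster
    sil[a] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)  # which.max takes the first (smallest k) on ties
  list(k = ks[best], cluster = fits[[best]],
       silhouette = setNames(sil, ks))
}

# Per-cluster quotas for one subgraph: floor(maxNodes / k) each, remainder
# slots to the largest clusters, shortfall from clusters smaller than their
# quota redistributed over clusters that still have spare members.
.clusterQuotas <- function(clusterSizes, maxNodes) {
  k <- length(clusterSizes)
  quota <- rep(maxNodes %/% k, k)
  r <- maxNodes - sum(quota)
  if (r > 0) {
    extra <- order(-clusterSizes, seq_len(k))[seq_len(r)]
    quota[extra] <- quota[extra] + 1L
  }
  take <- pmin(quota, clusterSizes)
  shortfall <- sum(quota) - sum(take)
  while (shortfall > 0) {
    spare <- which(take < clusterSizes)
    if (!length(spare)) break
    spare <- spare[order(-(clusterSizes[spare] - take[spare]))]
    add <- spare[seq_len(min(shortfall, length(spare)))]
    take[add] <- take[add] + 1L
    shortfall <- shortfall - length(add)
  }
  take
}

# Extract the induced subgraph of `graph` on `nodes` and recompute the
# subgraph-level consensus feature columns from the tm/qs matrices.
.induceSubgraph <- function(graph, nodes, tmValues, qsValues) {
  nodes <- sort(as.integer(nodes))
  ns <- length(nodes)
  X <- graph@nodeFeatures[nodes, , drop = FALSE]
  if (ns > 1L) {
    X[, "subgraph_mean_tm"] <-
      .rowMeanOffDiagonal(tmValues[nodes, nodes, drop = FALSE])
    X[, "subgraph_mean_qs"] <-
      .rowMeanOffDiagonal(qsValues[nodes, nodes, drop = FALSE])
  }
  A <- graph@adjacency[nodes, nodes, drop = FALSE]
  keep <- graph@edgeIndex[, 1L] %in% nodes & graph@edgeIndex[, 2L] %in% nodes
  eg <- graph@edgeIndex[keep, , drop = FALSE]
  local <- match(eg, nodes)
  eIdx <- matrix(as.integer(local), ncol = 2L,
                 dimnames = list(NULL, c("i", "j")))
  list(nodes = nodes, ids = graph@ids[nodes], adjacency = A,
       nodeFeatures = X, edgeIndex = eIdx,
       edgeFeatures = graph@edgeFeatures[keep, , drop = FALSE])
}

#' Sample cluster-balanced subgraphs
#'
#' Implements structural-similarity-based subgraph sampling. When the
#' average pairwise similarity of the pool is below
#' \code{pssModeThreshold}, decoys are K-means-clustered on their
#' similarity rows (cluster number chosen by silhouette) and each subgraph
#' draws a near-equal number of decoys from every cluster, so that one
#' large cluster of mutually similar mediocre models cannot dominate. At or
#' above the threshold (easy pools), subgraphs are uniform random draws.
#' Pools no larger than \code{maxNodes} yield the full graph in every
#' subgraph. After the requested number of draws a coverage-repair pass
#' appends subgraphs for any decoy not yet included, so aggregation always
#' has at least one prediction per decoy.
#'
#' Sampling is without replacement within a subgraph and independent across
#' subgraphs; subgraph-level mean-TM/QS node features are recomputed over
#' each subgraph's nodes.
#'
#' @param graph A [ModelGraph-class].
#' @param tm The pool's TM [PairwiseMatrix-class].
#' @param qs The pool's QS [PairwiseMatrix-class].
#' @param config A [samplerConfig()].
#' @return A list with \code{subgraphs} (list of induced subgraph lists
#'   with elements \code{nodes}, \code{ids}, \code{adjacency},
#'   \code{nodeFeatures}, \code{edgeIndex}, \code{edgeFeatures}),
#'   \code{mode} (\code{"balanced"} or \code{"uniform"}), \code{averagePSS},
#'   \code{cluster} (assignment, or NULL in uniform mode) and \code{k}.
#' @export
sampleSubgraphs <- function(graph, tm, qs, config = samplerConfig()) {
  stopifnot(is(graph, "ModelGraph"))
  n <- length(graph@ids)
  tmV <- .alignMatrix(tm, graph@ids)
  qsV <- .alignMatrix(qs, graph@ids)
  pss <- mean(tmV[upper.tri(tmV)])
  balanced <- pss < config$pssModeThreshold
  clu <- NULL
  k <- 1L
  if (balanced && n > config$maxNodes) {
    cfg <- config
    # guard: pools too small to cluster fall back to uniform draws
    if (n - 1L >= cfg$kMin) {
      sel <- chooseKSilhouette(
        PairwiseMatrix("tm", graph@ids, tmV), cfg)
      clu <- sel$cluster
      k <- sel$k
    } else balanced <- FALSE
  }
  members <- if (!is.null(clu)) split(seq_len(n), clu) else NULL

  set.seed(.deriveSeed(config$seed, 202L))
  drawOne <- function() {
    if (n <= config$maxNodes) return(seq_len(n))
    if (!balanced || is.null(members))
      return(sample.int(n, config$maxNodes))
    take <- .clusterQuotas(lengths(members), config$maxNodes)
    unlist(lapply(seq_along(members), function(c.)
      if (take[c.] >= length(members[[c.]])) members[[c.]]
      else sample(members[[c.]], take[c.])), use.names = FALSE)
  }
  nodeSets <- lapply(seq_len(config$nSubgraphs), function(s) drawOne())

  # coverage repair: every decoy must appear in at least one subgraph
  covered <- rep(FALSE, n)
  for (s in nodeSets) covered[s] <- TRUE
  while (!all(covered)) {
    miss <- which(!covered)
    seedNodes <- head(miss, config$maxNodes)
    extra <- seedNodes
    if (length(extra) < config$maxNodes && n > length(extra)) {
      others <- setdiff(drawOne(), extra)
      extra <- c(extra, head(others, config$maxNodes - length(extra)))
    }
    nodeSets[[length(nodeSets) + 1L]] <- extra
    covered[extra] <- TRUE
  }

  subgraphs <- lapply(nodeSets, function(s)
    .induceSubgraph(graph, s, tmV, qsV))
  list(subgraphs = subgraphs,
       mode = if (balanced) "balanced" else "uniform",
       averagePSS = pss, cluster = clu, k = k)
}
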