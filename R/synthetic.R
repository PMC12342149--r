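#' Synthetic decoy-pool scenarios
#'
#' Generates decoy pools with planted structural clusters so every stage of
#' the pipeline can be exercised without real structure comparisons. Each
#' cluster is a group of mutually similar decoys with a characteristic true
#' quality; each decoy has a 1-D latent deviation from its cluster center
#' that drives both its true TM-score and its similarity to cluster mates,
#' giving block-structured pairwise matrices with tunable within- and
#' between-cluster similarity.
#'
#' Presets:
#' \describe{
#'   \item{central_tendency}{A dominant cluster of 180 mediocre decoys
#'     (quality 0.60) plus 20 high-quality decoys (0.95): the adversarial
#'     composition on which plain consensus scoring tops out a mediocre
#'     model.}
#'   \item{recoverable}{Three clusters (100/60/40 decoys, qualities
#'     0.55/0.70/0.85): a learnable mixed pool.}
#'   \item{balanced}{Two equal clusters (100/100, qualities 0.60/0.80).}
#'   \item{easy_high_pss}{One tight cluster of 150 decoys at quality 0.85:
#'     average pairwise similarity at or above 0.8, the uniform-sampling
#'     branch.}
#' }
#'
#' @param name Preset name, or \code{"custom"} with explicit arguments.
#' @param clusterSizes,clusterQualities,clusterSpreads Per-cluster decoy
#'   count, center true TM-score, and within-cluster latent spread (SD).
#' @param crossClusterSim Typical pairwise similarity between decoys of
#'   different clusters.
#' @param withinSimScale Factor mapping latent distance to similarity loss
#'   within a cluster (similarity = 1 - scale * |latent difference|).
#' @param singleModelNoiseSd SD of the Gaussian noise added to true
#'   TM-scores to produce single-model quality scores.
#' @param qsCorrelation Weight mixing the TM matrix with independent noise
#'   to produce the QS matrix.
#' @param nativeLength Target sequence length carried by the pool.
#' @param seed Root seed; all draws derive from it.
#' @return A list of class \code{"SyntheticScenario"}.
#' @export
syntheticScenario <- function(name = c("central_tendency", "recoverable",
                                       "balanced", "easy_high_pss",
                                       "custom"),
                              clusterSizes = NULL,
                              clusterQualities = NULL,
                              clusterSpreads = NULL,
                              crossClusterSim = NULL,
                              withinSimScale = NULL,
                              singleModelNoiseSd = 0.1,
                              qsCorrelation = 0.8,
                              nativeLength = 200L,
                              seed = 1L) {
  name <- match.arg(name)
  preset <- switch(name,
    central_tendency = list(sizes = c(180L, 20L), q = c(0.60, 0.95),
                            sp = c(0.04, 0.02), cross = 0.3, scale = 3),
    recoverable = list(sizes = c(100L, 60L, 40L), q = c(0.55, 0.70, 0.85),
                       sp = c(0.04, 0.04, 0.03), cross = 0.3, scale = 3),
    balanced = list(sizes = c(100L, 100L), q = c(0.60, 0.80),
                    sp = c(0.04, 0.03), cross = 0.35, scale = 3),
    easy_high_pss = list(sizes = 150L, q = 0.85, sp = 0.03, cross = 0.3,
                         scale = 1),
    custom = list(sizes = NULL, q = NULL, sp = NULL, cross = 0.3,
                  scale = 3))
  clusterSizes <- as.integer(clusterSizes %||% preset$sizes)
  clusterQualities <- clusterQualities %||% preset$q
  clusterSpreads <- clusterSpreads %||% preset$sp
  crossClusterSim <- crossClusterSim %||% preset$cross
  withinSimScale <- withinSimScale %||% preset$scale
  if (is.null(clusterSizes) || any(clusterSizes < 1L))
    stop("cluster sizes must be positive integers")
  k <- length(clusterSizes)
  if (length(clusterQualities) != k || length(clusterSpreads) != k)
    stop("clusterQualities and clusterSpreads must align with clusterSizes")
  if (any(clusterQualities < 0) || any(clusterQualities > 1))
    stop("cluster center qualities must lie in [0, 1]")
  .assertScalarNumber(crossClusterSim, "crossClusterSim", 0, 1)
  .assertScalarNumber(singleModelNoiseSd, "singleModelNoiseSd", 0, Inf)
  .assertScalarNumber(qsCorrelation, "qsCorrelation", 0, 1)
  structure(list(name = name, nDecoys = sum(clusterSizes),
                 clusterSizes = clusterSizes,
                 clusterQualities = clusterQualities,
                 clusterSpreads = clusterSpreads,
                 crossClusterSim = crossClusterSim,
                 withinSimScale = withinSimScale,
                 singleModelNoiseSd = singleModelNoiseSd,
                 qsCorrelation = qsCorrelation,
                 nativeLength = as.integer(nativeLength),
                 seed = as.integer(seed)),
            class = "SyntheticScenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic decoy pool
#'
#' Draws one pool from a [syntheticScenario()]: true TM-score labels,
#' pairwise TM and QS matrices, an integer common-interface matrix, and
#' noisy single-model score tables (ICPS, EnQA, DProQA, VoroIF-GNN,
#' GCPNet-EMA), all satisfying the corresponding class invariants exactly.
#'
#' @param scenario A [syntheticScenario()].
#' @param targetId Target identifier for the pool.
#' @return A list with \code{pool} ([DecoyPool-class]), \code{matrices}
#'   (named list: tm, qs, common_interfaces), \code{scores} (named list of
#'   [ScoreTable-class]), \code{cluster} (planted assignment) and
#'   \code{scenario}.
#' @examples
#' gp <- generatePool(syntheticScenario("central_tendency", seed = 7))
#' gp$pool
#' @export
generatePool <- function(scenario, targetId = "synthetic") {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  n <- scenario$nDecoys
  k <- length(scenario$clusterSizes)
  clu <- rep(seq_len(k), times = scenario$clusterSizes)
  ids <- sprintf("%s_d%03d", targetId, seq_len(n))

  set.seed(.deriveSeed(scenario$seed, 1L))
  eps <- rnorm(n, 0, scenario$clusterSpreads[clu])
  yTrue <- .clip01(scenario$clusterQualities[clu] + eps)

  # pairwise TM: within clusters similarity decays with latent distance;
  # between clusters it hovers around crossClusterSim
  set.seed(.deriveSeed(scenario$seed, 2L))
  same <- outer(clu, clu, "==")
  within <- 1 - scenario$withinSimScale * abs(outer(eps, eps, "-"))
  crossNoise <- matrix(0, n, n)
  crossNoise[upper.tri(crossNoise)] <-
    rnorm(n * (n - 1) / 2, 0, 0.02)
  crossNoise <- crossNoise + t(crossNoise)
  between <- scenario$crossClusterSim + crossNoise
  tmV <- .clip01(ifelse(same, within, between))
  diag(tmV) <- 1
  dimnames(tmV) <- list(ids, ids)

  set.seed(.deriveSeed(scenario$seed, 3L))
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- runif(n * (n - 1) / 2)
  noise <- noise + t(noise)
  qsV <- .clip01(scenario$qsCorrelation * tmV +
                   (1 - scenario$qsCorrelation) * noise)
  diag(qsV) <- 1
  dimnames(qsV) <- list(ids, ids)

  ciV <- round(tmV * 5)
  diag(ciV) <- 0
  dimnames(ciV) <- list(ids, ids)

  scoreNames <- c("icps", "enqa", "dproqa", "voroif_gnn", "gcpnet_ema")
  scores <- list()
  for (a in seq_along(scoreNames)) {
    set.seed(.deriveSeed(scenario$seed, 10L + a))
    scores[[scoreNames[a]]] <- ScoreTable(
      scoreNames[a],
      setNames(.clip01(yTrue + rnorm(n, 0, scenario$singleModelNoiseSd)),
               ids))
  }

  pool <- DecoyPool(targetId, scenario$nativeLength, ids,
                    trueTM = yTrue)
  list(pool = pool,
       matrices = list(
         tm = PairwiseMatrix("tm", ids, tmV),
         qs = PairwiseMatrix("qs", ids, qsV),
         common_interfaces = PairwiseMatrix("common_interfaces", ids, ciV)),
       scores = scores,
       cluster = setNames(clu, ids),
       scenario = scenario)
}

#' Generate a reproducible multi-target benchmark
#'
#' Draws \code{nTargets} synthetic targets whose presets cycle through
#' \code{scenarioMix}, each with a seed derived from the root seed, and
#' records the composition in a manifest.
#'
#' @param nTargets Number of targets (at least 2).
#' @param scenarioMix Character vector of preset names recycled across
#'   targets (default an even rotation of all four presets).
#' @param seed Root seed.
#' @return A list with \code{targets} (list of [generatePool()] results)
#'   and \code{manifest} (data.frame: target_id, preset, n_decoys, seed).
#' @export
generateBenchmark <- function(nTargets,
                              scenarioMix = c("central_tendency",
                                              "recoverable", "balanced",
                                              "easy_high_pss"),
                              seed = 1L) {
  .assertScalarNumber(nTargets, "nTargets", 2, Inf)
  presets <- rep(scenarioMix, length.out = nTargets)
  targets <- vector("list", nTargets)
  for (a in seq_len(nTargets)) {
    tid <- sprintf("SYN%03d", a)
    sc <- syntheticScenario(presets[a],
                            seed = .deriveSeed(seed, 1000L + a))
    targets[[a]] <- generatePool(sc, tid)
  }
  manifest <- data.frame(
    target_id = vapply(targets, function(t) t$pool@targetId, ""),
    preset = presets,
    n_decoys = vapply(targets, function(t) length(t$pool@decoyIds), 0L),
    seed = vapply(targets, function(t) t$scenario$seed, 0L))
  list(targets = targets, manifest = manifest)
}
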