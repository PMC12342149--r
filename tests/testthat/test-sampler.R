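ns <- asNamespace("GraphEMA")

test_that("average pairwise similarity is the mean over unordered pairs", {
  ids <- c("a", "b", "c")
  v <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3,
              dimnames = list(ids, ids))
  expect_equal(averagePSS(PairwiseMatrix("tm", ids, v)), 0.4)
  one <- matrix(1, 3, 3, dimnames = list(ids, ids))
  expect_equal(averagePSS(PairwiseMatrix("tm", ids, one)), 1)
  expect_error(averagePSS(PairwiseMatrix("tm", "a",
                                         matrix(1, 1, 1,
                                                dimnames = list("a", "a")))),
               "at least 2")
})

test_that("silhouette selection recovers planted cluster numbers", {
  makeBlobs <- function(sizes, seed) {
    n <- sum(sizes)
    clu <- rep(seq_along(sizes), sizes)
    set.seed(seed)
    v <- matrix(0.1 + runif(n * n, -0.05, 0.05), n, n)
    v <- (v + t(v)) / 2
    same <- outer(clu, clu, "==")
    v[same] <- 0.9
    diag(v) <- 1
    ids <- sprintf("d%03d", 1:n)
    dimnames(v) <- list(ids, ids)
    PairwiseMatrix("tm", ids, v)
  }
  sel2 <- chooseKSilhouette(makeBlobs(c(20, 20), 1),
                            samplerConfig(seed = 1))
  expect_equal(sel2$k, 2L)
  sel3 <- chooseKSilhouette(makeBlobs(c(15, 15, 15), 2),
                            samplerConfig(seed = 2))
  expect_equal(sel3$k, 3L)
  expect_equal(length(sel3$cluster), 45L)
  # n = 3 admits only k = 2
  sel <- chooseKSilhouette(tmMatrix(randomSimMatrix(3, 3)),
                           samplerConfig(seed = 3))
  expect_equal(sel$k, 2L)
  # deterministic given the seed
  selA <- chooseKSilhouette(makeBlobs(c(20, 20), 4),
                            samplerConfig(seed = 9))
  selB <- chooseKSilhouette(makeBlobs(c(20, 20), 4),
                            samplerConfig(seed = 9))
  expect_identical(selA, selB)
})

test_that("cluster quotas are balanced with remainder to the largest clusters", {
  expect_equal(ns$.clusterQuotas(c(100, 100), 50), c(25, 25))
  expect_equal(ns$.clusterQuotas(c(90, 60, 50), 50), c(17, 17, 16))
  # small cluster contributes everything; shortfall goes elsewhere
  expect_equal(ns$.clusterQuotas(c(180, 5), 50), c(45, 5))
  expect_equal(sum(ns$.clusterQuotas(c(3, 4, 200), 50)), 50)
})

prepSampled <- function(preset, nSub = 40, seed = 3, maxNodes = 50) {
  gp <- generatePool(syntheticScenario(preset, seed = seed))
  g <- buildModelGraph(gp$pool, gp$matrices, gp$scores,
                       featureSpec("basic"))
  sam <- sampleSubgraphs(g, gp$matrices$tm, gp$matrices$qs,
                         samplerConfig(maxNodes = maxNodes,
                                       nSubgraphs = nSub, seed = seed))
  list(gp = gp, g = g, sam = sam)
}

test_that("subgraphs respect the node cap and cover every decoy", {
  out <- prepSampled("central_tendency", nSub = 40, seed = 3)
  sizes <- vapply(out$sam$subgraphs, function(s) length(s$nodes), 0L)
  expect_true(all(sizes == 50))  # pool larger than the cap: exactly 50
  covered <- sort(unique(unlist(lapply(out$sam$subgraphs, `[[`, "nodes"))))
  expect_equal(covered, seq_along(decoyIds(out$g)))
})

test_that("pools at or below the cap give the full graph in every subgraph", {
  gp <- generatePool(syntheticScenario("custom",
                                       clusterSizes = 30L,
                                       clusterQualities = 0.7,
                                       clusterSpreads = 0.05,
                                       seed = 4))
  g <- buildModelGraph(gp$pool, gp$matrices, gp$scores,
                       featureSpec("basic"))
  sam <- sampleSubgraphs(g, gp$matrices$tm, gp$matrices$qs,
                         samplerConfig(nSubgraphs = 5, seed = 4))
  expect_true(all(vapply(sam$subgraphs, function(s)
    identical(s$nodes, 1:30), TRUE)))
})

test_that("the 0.8 average-similarity boundary switches the sampling branch", {
  hard <- prepSampled("central_tendency", nSub = 10, seed = 5)
  expect_lt(hard$sam$averagePSS, 0.8)
  expect_identical(hard$sam$mode, "balanced")
  expect_gte(hard$sam$k, 2L)

  easy <- prepSampled("easy_high_pss", nSub = 10, seed = 5)
  expect_gte(easy$sam$averagePSS, 0.8)
  expect_identical(easy$sam$mode, "uniform")
  expect_null(easy$sam$cluster)
})

test_that("balanced sampling draws near-equal planted-cluster counts", {
  out <- prepSampled("balanced", nSub = 30, seed = 6)
  planted <- out$gp$cluster
  for (s in out$sam$subgraphs) {
    counts <- table(planted[s$nodes])
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("sampling is deterministic given the seed", {
  a <- prepSampled("recoverable", nSub = 15, seed = 7)
  b <- prepSampled("recoverable", nSub = 15, seed = 7)
  expect_identical(lapply(a$sam$subgraphs, `[[`, "nodes"),
                   lapply(b$sam$subgraphs, `[[`, "nodes"))
  c <- prepSampled("recoverable", nSub = 15, seed = 8)
  expect_false(identical(lapply(a$sam$subgraphs, `[[`, "nodes"),
                         lapply(c$sam$subgraphs, `[[`, "nodes")))
})

test_that("subgraph-level consensus features are recomputed per subgraph", {
  out <- prepSampled("central_tendency", nSub = 5, seed = 9)
  tmV <- similarityValues(out$gp$matrices$tm)
  sub <- out$sam$subgraphs[[1]]
  i <- sub$nodes[3]
  others <- setdiff(sub$nodes, i)
  expect_equal(unname(sub$nodeFeatures[3, "subgraph_mean_tm"]),
               mean(tmV[i, others]), tolerance = 1e-12)
  # full-pool subgraph reduces to the full-graph feature
  gp <- generatePool(syntheticScenario("custom", clusterSizes = 20L,
                                       clusterQualities = 0.6,
                                       clusterSpreads = 0.05, seed = 10))
  g <- buildModelGraph(gp$pool, gp$matrices, gp$scores,
                       featureSpec("basic"))
  sam <- sampleSubgraphs(g, gp$matrices$tm, gp$matrices$qs,
                         samplerConfig(nSubgraphs = 2, seed = 10))
  X <- sam$subgraphs[[1]]$nodeFeatures
  expect_equal(X[, "subgraph_mean_tm"], X[, "graph_mean_tm"],
               tolerance = 1e-12)
})

test_that("subgraph edge features restrict the full-graph edge set", {
  out <- prepSampled("recoverable", nSub = 3, seed = 11)
  g <- out$g
  sub <- out$sam$subgraphs[[1]]
  # every subgraph edge exists in the full graph between the same decoys
  full <- paste(decoyIds(g)[edgeIndex(g)[, 1]],
                decoyIds(g)[edgeIndex(g)[, 2]])
  local <- paste(sub$ids[sub$edgeIndex[, 1]],
                 sub$ids[sub$edgeIndex[, 2]])
  expect_true(all(local %in% full))
  # and carries the same features
  pick <- match(local, full)
  expect_equal(sub$edgeFeatures, edgeFeatures(g)[pick, , drop = FALSE],
               ignore_attr = TRUE)
})
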