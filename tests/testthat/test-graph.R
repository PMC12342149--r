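test_that("edges require the pairwise TM-score to strictly exceed the threshold", {
  ids <- c("a", "b", "c")
  v <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.2, 0.5, 0.2, 1), 3,
              dimnames = list(ids, ids))
  e <- buildEdges(PairwiseMatrix("tm", ids, v))
  # 0.6 > 0.5 makes an edge; exactly 0.5 does not
  expect_equal(nrow(e), 1L)
  expect_equal(unname(e[1, ]), c(1L, 2L))
  expect_error(buildEdges(PairwiseMatrix("tm", ids, v), threshold = 1.2),
               "threshold")
})

test_that("edge sets match exhaustive pair enumeration on random matrices", {
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    pm <- tmMatrix(randomSimMatrix(n, seed = seed))
    e <- buildEdges(pm, 0.5)
    v <- similarityValues(pm)
    expected <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (v[i, j] > 0.5) expected[[length(expected) + 1]] <- c(i, j)
    expected <- if (length(expected)) do.call(rbind, expected) else
      matrix(integer(), 0, 2)
    expect_equal(unname(e), unname(expected), ignore_attr = TRUE)
  }
})

test_that("length normalization scales by decoy/native ratio and clips", {
  expect_equal(normalizeSingleModelScore(0.9, 200, 200), 0.9)
  expect_equal(normalizeSingleModelScore(0.8, 100, 200), 0.4)
  expect_equal(normalizeSingleModelScore(1.0, 250, 200), 1.0)  # clipped
  expect_equal(normalizeSingleModelScore(1.0, 250, 200, bounded = FALSE),
               1.25)
  expect_error(normalizeSingleModelScore(0.5, 100, 0), "nativeLength")
})

test_that("consensus node features average pairwise similarity without self", {
  ds <- tinyDataset(3)
  ids <- decoyIds(ds$pool)
  tmv <- matrix(c(1, 0.6, 0.8,
                  0.6, 1, 0.4,
                  0.8, 0.4, 1), 3, byrow = TRUE,
                dimnames = list(ids, ids))
  ds$matrices$tm <- PairwiseMatrix("tm", ids, tmv)
  X <- computeNodeFeatures(ds$pool, ds$matrices, ds$scores,
                           featureSpec("basic"))
  expect_equal(unname(X[ids[1], "graph_mean_tm"]), 0.7)  # (0.6 + 0.8) / 2
  expect_equal(unname(X[ids[2], "graph_mean_tm"]), 0.5)
  # a pool decoy absent from the matrix is a hard error
  dsBad <- tinyDataset(4)
  expect_error(
    computeNodeFeatures(dsBad$pool, ds$matrices, dsBad$scores,
                        featureSpec("basic")),
    "missing decoys")
})

test_that("all-identical similarities give consensus feature 1 everywhere", {
  ds <- tinyDataset(5)
  ids <- decoyIds(ds$pool)
  one <- matrix(1, 5, 5, dimnames = list(ids, ids))
  ds$matrices$tm <- PairwiseMatrix("tm", ids, one)
  ds$matrices$qs <- PairwiseMatrix("qs", ids, one)
  X <- computeNodeFeatures(ds$pool, ds$matrices, ds$scores,
                           featureSpec("basic"))
  expect_true(all(X[, c("graph_mean_tm", "graph_mean_qs",
                        "subgraph_mean_tm", "subgraph_mean_qs")] == 1))
})

test_that("missing single-model scores are median-imputed and masked", {
  ds <- tinyDataset(6)
  ids <- decoyIds(ds$pool)
  sc <- ds$scores$enqa@scores
  sc[2] <- NA
  ds$scores$enqa <- ScoreTable("enqa", sc)
  X <- computeNodeFeatures(ds$pool, ds$matrices, ds$scores,
                           featureSpec("basic"))
  expect_equal(unname(X[, "enqa_missing"]),
               c(0, 1, 0, 0, 0, 0))
  norm <- normalizeSingleModelScore(sc[-2], 100, 100)
  expect_equal(unname(X[2, "enqa"]), unname(median(norm)))
  # a completely absent scorer: all masked, neutral fill
  ds$scores$icps <- NULL
  X2 <- computeNodeFeatures(ds$pool, ds$matrices, ds$scores,
                            featureSpec("basic"))
  expect_true(all(X2[, "icps_missing"] == 1))
  expect_true(all(X2[, "icps"] == 0.5))
})

test_that("node features are permutation-equivariant and bounded", {
  ds <- tinyDataset(8, seed = 21)
  spec <- featureSpec("basic")
  X <- computeNodeFeatures(ds$pool, ds$matrices, ds$scores, spec)
  expect_true(all(X >= 0 & X <= 1))
  set.seed(22)
  perm <- sample(8)
  ids <- decoyIds(ds$pool)[perm]
  poolP <- DecoyPool("TT01", 100L, ids,
                     trueTM = unname(trueTM(ds$pool)[ids]))
  permMat <- function(pm)
    PairwiseMatrix(metricName(pm), ids,
                   similarityValues(pm)[ids, ids])
  dsP <- list(matrices = lapply(ds$matrices, permMat), scores = ds$scores)
  XP <- computeNodeFeatures(poolP, dsP$matrices, dsP$scores, spec)
  expect_equal(XP, X[perm, , drop = FALSE], ignore_attr = TRUE)
})

test_that("edge features carry scaled interface counts plus similarities", {
  ids <- c("x", "y")
  tmv <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(ids, ids))
  qsv <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(ids, ids))
  civ <- matrix(c(0, 3, 3, 0), 2, dimnames = list(ids, ids))
  mats <- list(tm = PairwiseMatrix("tm", ids, tmv),
               qs = PairwiseMatrix("qs", ids, qsv),
               common_interfaces = PairwiseMatrix("common_interfaces",
                                                  ids, civ))
  e <- matrix(c(1L, 2L), 1)
  E <- computeEdgeFeatures(e, ids, mats, featureSpec("basic"),
                           interfaceCap = 10)
  expect_equal(unname(E[1, ]), c(0.3, 0.9, 0.8))
  # identical decoys: similarity tail is [1, 1]
  tmv1 <- matrix(1, 2, 2, dimnames = list(ids, ids))
  mats$tm <- PairwiseMatrix("tm", ids, tmv1)
  mats$qs <- PairwiseMatrix("qs", ids, tmv1)
  E1 <- computeEdgeFeatures(e, ids, mats, featureSpec("basic"))
  expect_equal(unname(E1[1, c("tm", "qs")]), c(1, 1))
  # counts above the cap clip to 1
  civ20 <- matrix(c(0, 20, 20, 0), 2, dimnames = list(ids, ids))
  mats$common_interfaces <- PairwiseMatrix("common_interfaces", ids, civ20)
  expect_equal(unname(computeEdgeFeatures(e, ids, mats,
                                          featureSpec("basic"))[1, 1]), 1)
})

test_that("the advanced variant demands its interface matrices", {
  ds <- tinyDataset(5)
  expect_error(
    buildModelGraph(ds$pool, ds$matrices, ds$scores,
                    featureSpec("advanced")),
    "missing: dockq_ave")
  ids <- decoyIds(ds$pool)
  for (metric in c("dockq_ave", "dockq_wave", "cad"))
    ds$matrices[[metric]] <-
      PairwiseMatrix(metric, ids, randomSimMatrix(5, seed = 31))
  g <- buildModelGraph(ds$pool, ds$matrices, ds$scores,
                       featureSpec("advanced"))
  expect_true(all(c("graph_mean_dockq_ave", "graph_mean_cad") %in%
                    colnames(nodeFeatures(g))))
  expect_true(all(c("dockq_ave", "dockq_wave", "cad") %in%
                    colnames(edgeFeatures(g))))
})

test_that("feature variants nest: basic within gcp within advanced", {
  b <- featureSpec("basic"); g <- featureSpec("gcp")
  a <- featureSpec("advanced")
  expect_true(all(b$nodeFeatureNames %in% g$nodeFeatureNames))
  expect_true(all(g$nodeFeatureNames %in% a$nodeFeatureNames))
  expect_identical(b$edgeFeatureNames, g$edgeFeatureNames)
  expect_true(all(g$edgeFeatureNames %in% a$edgeFeatureNames))
})

test_that("the model graph keeps isolated nodes and symmetric adjacency", {
  ds <- tinyDataset(7, seed = 41)
  ids <- decoyIds(ds$pool)
  v <- similarityValues(ds$matrices$tm)
  v[7, ] <- v[, 7] <- 0.1  # isolate the last decoy
  diag(v) <- 1
  ds$matrices$tm <- PairwiseMatrix("tm", ids, v)
  g <- buildModelGraph(ds$pool, ds$matrices, ds$scores)
  A <- adjacencyMatrix(g)
  expect_identical(A, t(A))
  expect_false(any(diag(A)))
  expect_equal(sum(A[7, ]), 0)
  expect_equal(length(decoyIds(g)), 7L)
})
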