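ns <- asNamespace("GraphEMA")

test_that("feature embedding equals a hand-rolled MLP oracle", {
  cfg <- tinyTransformerConfig(seed = 2)
  sub <- randomSubgraph(4, seed = 2)
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  emb <- ns$.embedForward(params$nodeEmbed, sub$nodeFeatures)
  slope <- 0.01
  for (i in seq_len(4)) {
    x <- sub$nodeFeatures[i, ]
    h1 <- as.vector(x %*% params$nodeEmbed$W1) + params$nodeEmbed$b1
    h1 <- ifelse(h1 > 0, h1, slope * h1)
    h2 <- as.vector(h1 %*% params$nodeEmbed$W2) + params$nodeEmbed$b2
    expect_equal(unname(emb$out[i, ]), unname(h2), tolerance = 1e-6)
  }
  # identical inputs embed identically; zero weights embed to zero
  subEq <- sub
  subEq$nodeFeatures[2, ] <- subEq$nodeFeatures[1, ]
  embEq <- ns$.embedForward(params$nodeEmbed, subEq$nodeFeatures)
  expect_equal(embEq$out[1, ], embEq$out[2, ])
  zeroP <- lapply(params$nodeEmbed, function(w) w * 0)
  expect_true(all(ns$.embedForward(zeroP, sub$nodeFeatures)$out == 0))
})

test_that("attention matches a dense brute-force oracle on random graphs", {
  for (seed in 1:40) {
    cfg <- tinyTransformerConfig(seed = seed)
    n <- sample(3:10, 1)
    sub <- randomSubgraph(n, seed = seed + 100)
    params <- initParameters(cfg, ncol(sub$nodeFeatures),
                             ncol(sub$edgeFeatures))
    fw <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE,
                              keepCache = TRUE)
    cc <- fw$cache$layers[[1]]
    ref <- attentionOracle(cc$Hl, cc$El, sub, params$layers[[1]],
                           cfg$nHeads, cfg$dK)
    for (h in seq_len(cfg$nHeads)) {
      expect_equal(cc$alphas[[h]], ref$alphas[[h]], tolerance = 1e-6)
      # probability rows over the allowed neighborhood
      expect_equal(unname(rowSums(cc$alphas[[h]])), rep(1, n),
                   tolerance = 1e-6)
      expect_true(all(cc$alphas[[h]] >= 0))
      # non-neighbors get exactly zero
      off <- !(sub$adjacency | diag(TRUE, n))
      expect_true(all(cc$alphas[[h]][off] == 0))
    }
  }
})

test_that("an isolated node attends only to itself", {
  cfg <- tinyTransformerConfig(seed = 5)
  sub <- randomSubgraph(5, pEdge = 0, seed = 5)  # no edges at all
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  fw <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE,
                            keepCache = TRUE)
  for (h in seq_len(cfg$nHeads))
    expect_equal(fw$cache$layers[[1]]$alphas[[h]], diag(5))
  # locality: perturbing node 2's features leaves node 1's score unchanged
  sub2 <- sub
  sub2$nodeFeatures[2, ] <- runif(ncol(sub$nodeFeatures))
  fw2 <- ns$.forwardSubgraph(params, cfg, sub2, train = FALSE)
  expect_equal(fw$yhat[1], fw2$yhat[1], tolerance = 1e-12)
})

test_that("uniform keys and biases give uniform attention over the neighborhood", {
  cfg <- transformerConfig(nLayers = 1, nHeads = 1, dNode = 4, dEdge = 2,
                           dK = 2, dropout = 0, seed = 6)
  # star: node 1 linked to 2, 3, 4
  sub <- randomSubgraph(4, pEdge = 0, seed = 6)
  sub$adjacency[1, 2:4] <- sub$adjacency[2:4, 1] <- TRUE
  sub$edgeIndex <- cbind(1L, 2:4)
  sub$edgeFeatures <- matrix(0.5, 3, ncol(sub$edgeFeatures),
                             dimnames = dimnames(sub$edgeFeatures))
  sub$nodeFeatures[] <- 0.5  # identical nodes -> identical keys
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  params$layers[[1]]$bSelf[] <- 0
  # force the self logit to equal the neighbor logits: with identical
  # nodes q.k is constant, so zero the edge bias as well
  params$layers[[1]]$wE[] <- 0
  fw <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE,
                            keepCache = TRUE)
  expect_equal(unname(fw$cache$layers[[1]]$alphas[[1]][1, ]),
               rep(0.25, 4), tolerance = 1e-12)
})

test_that("the forward pass is permutation-equivariant", {
  for (seed in 1:10) {
    cfg <- tinyTransformerConfig(seed = seed)
    sub <- randomSubgraph(6, seed = seed + 50)
    params <- initParameters(cfg, ncol(sub$nodeFeatures),
                             ncol(sub$edgeFeatures))
    y1 <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE)$yhat
    set.seed(seed)
    perm <- sample(6)
    inv <- order(perm)
    subP <- sub
    subP$nodeFeatures <- sub$nodeFeatures[perm, , drop = FALSE]
    subP$adjacency <- sub$adjacency[perm, perm]
    ei <- cbind(inv[sub$edgeIndex[, 1]], inv[sub$edgeIndex[, 2]])
    flip <- ei[, 1] > ei[, 2]
    ei[flip, ] <- ei[flip, c(2, 1)]
    subP$edgeIndex <- matrix(as.integer(ei), ncol = 2)
    subP$edgeFeatures <- sub$edgeFeatures
    y2 <- ns$.forwardSubgraph(params, cfg, subP, train = FALSE)$yhat
    expect_equal(y2, y1[perm], tolerance = 1e-6)
  }
})

test_that("outputs are deterministic in eval mode and bounded for random draws", {
  cfg <- tinyTransformerConfig(seed = 7, dropout = 0.2)
  sub <- randomSubgraph(8, seed = 7)
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  a <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE)$yhat
  b <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE)$yhat
  expect_identical(a, b)
  for (seed in 1:100) {
    cfgr <- tinyTransformerConfig(seed = seed)
    p <- initParameters(cfgr, ncol(sub$nodeFeatures),
                        ncol(sub$edgeFeatures))
    # scale some weights up to stress the sigmoid bound
    p$readout$R2 <- p$readout$R2 * 20
    yh <- ns$.forwardSubgraph(p, cfgr, sub, train = FALSE)$yhat
    expect_true(all(yh >= 0 & yh <= 1))
  }
})

test_that("edge updates are symmetric in their endpoints", {
  cfg <- tinyTransformerConfig(seed = 8)
  sub <- randomSubgraph(5, seed = 8)
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  fw <- ns$.forwardSubgraph(params, cfg, sub, train = FALSE,
                            keepCache = TRUE)
  # the edge stream stores one embedding per undirected edge; its update
  # input h_i + h_j is symmetric under endpoint exchange by construction
  cc <- fw$cache$layers[[1]]
  s <- sub$edgeIndex[, 1]; t. <- sub$edgeIndex[, 2]
  expect_equal(cc$Ssum, cc$Hl[s, ] + cc$Hl[t., ])
  expect_equal(cc$Ssum, cc$Hl[t., ] + cc$Hl[s, ])
})

test_that("autodiff gradients match finite differences", {
  set.seed(9)
  cfg <- tinyTransformerConfig(seed = 9)
  sub <- randomSubgraph(5, seed = 9)
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  y <- runif(5)
  lossOf <- function(p)
    totalLoss(y, ns$.forwardSubgraph(p, cfg, sub)$yhat, 1, 1)
  fw <- ns$.forwardSubgraph(params, cfg, sub, train = TRUE)
  dY <- ns$.totalLossGrad(y, fw$yhat, 1, 1)
  g <- ns$.backwardSubgraph(params, cfg, sub, fw$cache, dY)
  flat <- ns$.flattenParams(params)
  gflat <- ns$.flattenParams(g)
  set.seed(99)
  idx <- sample(length(flat), 10)
  h <- 1e-5
  for (i in idx) {
    p1 <- flat; p1[i] <- p1[i] + h
    p2 <- flat; p2[i] <- p2[i] - h
    num <- (lossOf(ns$.relistParams(p1, params)) -
              lossOf(ns$.relistParams(p2, params))) / (2 * h)
    denom <- max(abs(num), abs(gflat[i]), 1e-8)
    expect_lt(abs(num - gflat[i]) / denom, 1e-4)
  }
})

test_that("checkpoints round-trip through JSON and reject incompatibility", {
  cfg <- tinyTransformerConfig(seed = 10)
  sub <- randomSubgraph(6, seed = 10)
  params <- initParameters(cfg, ncol(sub$nodeFeatures),
                           ncol(sub$edgeFeatures))
  ck <- list(version = "graphema-checkpoint-1", params = params,
             config = cfg,
             nodeFeatureNames = colnames(sub$nodeFeatures),
             edgeFeatureNames = colnames(sub$edgeFeatures),
             bestEpoch = 3L, bestValLoss = 0.01, seed = 10L)
  f <- withr::local_tempfile(fileext = ".json")
  saveCheckpoint(ck, f)
  back <- loadCheckpoint(f)
  expect_equal(back$params, params, tolerance = 1e-15)
  expect_equal(predictSubgraph(back, sub),
               setNames(ns$.forwardSubgraph(params, cfg, sub)$yhat,
                        sub$ids))
  # a subgraph with different features fails loudly
  subBad <- randomSubgraph(6, nNodeF = 7, seed = 11)
  expect_error(predictSubgraph(back, subBad), "feature mismatch")
  # corrupting the version header fails loudly
  txt <- readLines(f)
  writeLines(gsub("graphema-checkpoint-1", "other-format", txt), f)
  expect_error(loadCheckpoint(f), "incompatible")
})
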