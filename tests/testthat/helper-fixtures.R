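# Fixture builders shared across the suite. Everything is generated in
# code: no stored data files.

# Symmetric similarity matrix with unit diagonal and values in [0, 1].
randomSimMatrix <- function(n, seed = 1, lo = 0, hi = 1) {
  set.seed(seed)
  u <- matrix(runif(n * n, lo, hi), n, n)
  m <- (u + t(u)) / 2
  diag(m) <- 1
  ids <- sprintf("d%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  m
}

tmMatrix <- function(values, ids = sprintf("d%02d", seq_len(nrow(values))),
                     metric = "tm") {
  dimnames(values) <- list(ids, ids)
  PairwiseMatrix(metric, ids, values)
}

# A small fully-specified pool with tm/qs/common-interface matrices and
# four single-model score tables, suitable for graph building.
tinyDataset <- function(n = 8, seed = 1) {
  ids <- sprintf("d%02d", seq_len(n))
  tm <- randomSimMatrix(n, seed)
  qs <- randomSimMatrix(n, seed + 1)
  ci <- round(tm * 4)
  diag(ci) <- 0
  set.seed(seed + 2)
  y <- runif(n)
  pool <- DecoyPool("TT01", 100L, ids, trueTM = y)
  scores <- lapply(c(icps = "icps", enqa = "enqa", dproqa = "dproqa",
                     voroif_gnn = "voroif_gnn"), function(sn)
    ScoreTable(sn, setNames(pmin(pmax(y + rnorm(n, 0, 0.05), 0), 1), ids)))
  list(pool = pool,
       matrices = list(tm = PairwiseMatrix("tm", ids, tm),
                       qs = PairwiseMatrix("qs", ids, qs),
                       common_interfaces =
                         PairwiseMatrix("common_interfaces", ids, ci)),
       scores = scores)
}

# Random subgraph in the exact form the transformer consumes.
randomSubgraph <- function(n = 6, nNodeF = 5, nEdgeF = 3, pEdge = 0.5,
                           seed = 1) {
  set.seed(seed)
  A <- matrix(FALSE, n, n)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < pEdge]
  A[on] <- TRUE
  A <- A | t(A)
  eIdx <- which(upper.tri(A) & A, arr.ind = TRUE)
  eIdx <- matrix(as.integer(eIdx), ncol = 2L)
  eIdx <- eIdx[order(eIdx[, 1], eIdx[, 2]), , drop = FALSE]
  nodeF <- matrix(runif(n * nNodeF), n, nNodeF,
                  dimnames = list(NULL, paste0("nf", seq_len(nNodeF))))
  edgeF <- matrix(runif(nrow(eIdx) * nEdgeF), nrow(eIdx), nEdgeF,
                  dimnames = list(NULL, paste0("ef", seq_len(nEdgeF))))
  list(nodes = seq_len(n), ids = sprintf("d%02d", seq_len(n)),
       adjacency = A, nodeFeatures = nodeF, edgeIndex = eIdx,
       edgeFeatures = edgeF)
}

tinyTransformerConfig <- function(seed = 1, dropout = 0)
  transformerConfig(nLayers = 2, nHeads = 2, dNode = 8, dEdge = 4,
                    dK = 3, dropout = dropout, seed = seed)

# Independent dense-matrix oracle for one round of edge-biased masked
# multi-head attention: explicit per-pair loops, no shared code with the
# implementation.
attentionOracle <- function(Hmat, Emat, sub, p, nHeads, dK) {
  n <- nrow(Hmat)
  d <- ncol(Hmat)
  dv <- d / nHeads
  out <- matrix(0, n, d)
  alphas <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    ck <- ((h - 1) * dK + 1):(h * dK)
    cv <- ((h - 1) * dv + 1):(h * dv)
    Q <- Hmat %*% p$Wq[, ck, drop = FALSE]
    K <- Hmat %*% p$Wk[, ck, drop = FALSE]
    V <- Hmat %*% p$Wv[, cv, drop = FALSE]
    edgeBias <- matrix(NA_real_, n, n)
    if (nrow(sub$edgeIndex))
      for (r in seq_len(nrow(sub$edgeIndex))) {
        i <- sub$edgeIndex[r, 1]; j <- sub$edgeIndex[r, 2]
        b <- sum(Emat[r, ] * p$wE[, h])
        edgeBias[i, j] <- b; edgeBias[j, i] <- b
      }
    al <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(sub$adjacency[i, ])
      logit <- numeric()
      for (j in nb)
        logit[as.character(j)] <-
          sum(Q[i, ] * K[j, ]) / sqrt(dK) + edgeBias[i, j]
      logit[as.character(i)] <-
        sum(Q[i, ] * K[i, ]) / sqrt(dK) + p$bSelf[h]
      w <- exp(logit - max(logit))
      w <- w / sum(w)
      for (j in names(w)) al[i, as.integer(j)] <- w[[j]]
      out[i, cv] <- colSums(sweep(V, 1, al[i, ], "*"))
    }
    alphas[[h]] <- al
  }
  list(alphas = alphas, out = out)
}
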