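#' Graph transformer configuration
#'
#' Architecture of the edge-biased graph transformer: feature-embedding
#' MLPs for nodes and edges, \code{nLayers} rounds of neighbor-masked
#' multi-head attention (scaled dot-product logits plus a learned linear
#' projection of the edge embedding as an additive bias; isolated nodes
#' attend to themselves through a learned self-bias), node and edge
#' residual updates with post-residual layer normalization, and a 2-layer
#' sigmoid readout bounding every node score to [0, 1].
#'
#' @param nLayers Number of transformer layers (default 3).
#' @param nHeads Attention heads (default 4); must divide \code{dNode}.
#' @param dNode Node embedding dimension (default 64).
#' @param dEdge Edge embedding dimension (default 32).
#' @param dK Key/query dimension per head (default 16).
#' @param dropout Dropout rate on MLP hidden activations, training mode
#'   only (default 0.1).
#' @param seed Integer seed for parameter initialization.
#' @return A validated list of class \code{"TransformerConfig"}.
#' @export
transformerConfig <- function(nLayers = 3L, nHeads = 4L, dNode = 64L,
                              dEdge = 32L, dK = 16L, dropout = 0.1,
                              seed = 1L) {
  .assertScalarNumber(nLayers, "nLayers", 1, Inf)
  .assertScalarNumber(nHeads, "nHeads", 1, Inf)
  .assertScalarNumber(dNode, "dNode", 1, Inf)
  .assertScalarNumber(dEdge, "dEdge", 1, Inf)
  .assertScalarNumber(dK, "dK", 1, Inf)
  .assertScalarNumber(dropout, "dropout", 0, 1 - 1e-12)
  if (as.integer(dNode) %% as.integer(nHeads) != 0L)
    stop("dNode must be divisible by nHeads")
  structure(list(nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
                 dNode = as.integer(dNode), dEdge = as.integer(dEdge),
                 dK = as.integer(dK), dropout = dropout,
                 seed = as.integer(seed)),
            class = "TransformerConfig")
}

#' Initialize transformer parameters
#'
#' Glorot-uniform initialization of every weight matrix; biases,
#' layer-norm shifts and attention self-biases start at zero, layer-norm
#' scales at one. Deterministic given \code{config$seed}.
#'
#' @param config A [transformerConfig()].
#' @param nNodeFeatures Number of raw node features.
#' @param nEdgeFeatures Number of raw edge features.
#' @return Nested parameter list (see source for layout).
#' @export
initParameters <- function(config, nNodeFeatures, nEdgeFeatures) {
  d <- config$dNode; de <- config$dEdge
  dk <- config$dK; H <- config$nHeads
  set.seed(.deriveSeed(config$seed, 303L))
  mlp <- function(nin, nhid, nout)
    list(W1 = .glorot(nin, nhid), b1 = numeric(nhid),
         W2 = .glorot(nhid, nout), b2 = numeric(nout))
  layer <- function()
    list(Wq = .glorot(d, H * dk), Wk = .glorot(d, H * dk),
         Wv = .glorot(d, d), wE = .glorot(de, H), bSelf = numeric(H),
         Wo = .glorot(d, d), bO = numeric(d),
         M1 = .glorot(d, d), c1 = numeric(d),
         M2 = .glorot(d, d), c2 = numeric(d),
         g1 = rep(1, d), be1 = numeric(d),
         P = .glorot(d, de),
         E1 = .glorot(de, de), f1 = numeric(de),
         E2 = .glorot(de, de), f2 = numeric(de),
         g2 = rep(1, de), be2 = numeric(de))
  list(nodeEmbed = mlp(nNodeFeatures, d, d),
       edgeEmbed = mlp(nEdgeFeatures, de, de),
       layers = lapply(seq_len(config$nLayers), function(l) layer()),
       readout = list(R1 = .glorot(d, d), r1 = numeric(d),
                      R2 = .glorot(d, 1L), r2 = numeric(1L)))
}

.embedForward <- function(p, X) {
  pre <- .addRowVec(X %*% p$W1, p$b1)
  a <- .lrelu(pre)
  out <- .addRowVec(a %*% p$W2, p$b2)
  list(out = out, pre = pre, a = a, X = X)
}

.embedBackward <- function(p, cache, dout) {
  da <- dout %*% t(p$W2)
  dpre <- da * .lreluGrad(cache$pre)
  list(grad = list(W1 = crossprod(cache$X, dpre), b1 = colSums(dpre),
                   W2 = crossprod(cache$a, dout), b2 = colSums(dout)),
       dX = dpre %*% t(p$W1))
}

.dropMask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(dim1 * dim2, 1L, 1 - p) / (1 - p), dim1, dim2)
}

# Forward pass over one subgraph. `sub` needs: nodeFeatures (n x F),
# edgeIndex (m x 2, i < j), edgeFeatures (m x Fe), adjacency (n x n
# logical). Returns per-node scores in [0, 1] plus (optionally) the cache
# required for the backward pass.
.forwardSubgraph <- function(params, config, sub, train = FALSE,
                             keepCache = train) {
  n <- nrow(sub$nodeFeatures)
  m <- nrow(sub$edgeIndex)
  H <- config$nHeads; dk <- config$dK; d <- config$dNode
  dv <- d %/% H
  drop <- if (train) config$dropout else 0
  s <- sub$edgeIndex[, 1L]; t. <- sub$edgeIndex[, 2L]
  allowed <- sub$adjacency | diag(TRUE, n)

  embN <- .embedForward(params$nodeEmbed, sub$nodeFeatures)
  embE <- .embedForward(params$edgeEmbed,
                        if (m) sub$edgeFeatures else
                          matrix(0, 0L, ncol(sub$edgeFeatures)))
  Hl <- embN$out
  El <- embE$out
  layerCaches <- vector("list", config$nLayers)

  for (l in seq_len(config$nLayers)) {
    p <- params$layers[[l]]
    Q <- Hl %*% p$Wq; K <- Hl %*% p$Wk; V <- Hl %*% p$Wv
    alphas <- vector("list", H)
    O <- matrix(0, n, d)
    for (h in seq_len(H)) {
      ck <- ((h - 1L) * dk + 1L):(h * dk)
      cv <- ((h - 1L) * dv + 1L):(h * dv)
      S <- tcrossprod(Q[, ck, drop = FALSE], K[, ck, drop = FALSE]) /
        sqrt(dk)
      logits <- S
      if (m) {
        bvec <- El %*% p$wE[, h]
        logits[cbind(s, t.)] <- logits[cbind(s, t.)] + bvec
        logits[cbind(t., s)] <- logits[cbind(t., s)] + bvec
      }
      diag(logits) <- diag(logits) + p$bSelf[h]
      logits[!allowed] <- -Inf
      a <- .maskedSoftmax(logits)
      alphas[[h]] <- a
      O[, cv] <- a %*% V[, cv, drop = FALSE]
    }
    attnOut <- .addRowVec(O %*% p$Wo, p$bO)
    U <- Hl + attnOut
    hid <- .addRowVec(U %*% p$M1, p$c1)
    act <- .lrelu(hid)
    mask1 <- .dropMask(n, d, drop)
    actd <- if (is.null(mask1)) act else act * mask1
    mlpOut <- .addRowVec(actd %*% p$M2, p$c2)
    lnN <- .layerNormForward(Hl + mlpOut, p$g1, p$be1)

    if (m) {
      Ssum <- Hl[s, , drop = FALSE] + Hl[t., , drop = FALSE]
      Pin <- El + Ssum %*% p$P
      ehid <- .addRowVec(Pin %*% p$E1, p$f1)
      eact <- .lrelu(ehid)
      mask2 <- .dropMask(m, config$dEdge, drop)
      eactd <- if (is.null(mask2)) eact else eact * mask2
      eout <- .addRowVec(eactd %*% p$E2, p$f2)
      lnE <- .layerNormForward(El + eout, p$g2, p$be2)
      Enext <- lnE$y
    } else {
      Ssum <- Pin <- ehid <- eact <- eactd <- NULL
      mask2 <- NULL; lnE <- NULL
      Enext <- El
    }

    if (keepCache)
      layerCaches[[l]] <- list(
        Hl = Hl, El = El, Q = Q, K = K, V = V, alphas = alphas, O = O,
        U = U, hid = hid, act = act, mask1 = mask1, actd = actd,
        lnN = lnN, Ssum = Ssum, Pin = Pin, ehid = ehid, eact = eact,
        eactd = eactd, mask2 = mask2, lnE = lnE)
    Hl <- lnN$y
    El <- Enext
  }

  ro <- params$readout
  z1 <- .addRowVec(Hl %*% ro$R1, ro$r1)
  za <- .lrelu(z1)
  mask3 <- .dropMask(n, d, drop)
  zad <- if (is.null(mask3)) za else za * mask3
  z <- as.vector(zad %*% ro$R2 + ro$r2)
  yhat <- .sigmoid(z)

  cache <- if (keepCache)
    list(embN = embN, embE = embE, layers = layerCaches, Hfinal = Hl,
         z1 = z1, za = za, mask3 = mask3, zad = zad, yhat = yhat,
         n = n, m = m, s = s, t = t., allowed = allowed)
  list(yhat = yhat, cache = cache)
}

# Backward pass over one subgraph. `dYhat` is the loss gradient w.r.t. the
# per-node sigmoid outputs. Returns the parameter gradient with the same
# nesting as `params`.
.backwardSubgraph <- function(params, config, sub, cache, dYhat) {
  H <- config$nHeads; dk <- config$dK; d <- config$dNode
  dv <- d %/% H
  n <- cache$n; m <- cache$m
  s <- cache$s; t. <- cache$t
  grads <- list(nodeEmbed = NULL, edgeEmbed = NULL,
                layers = vector("list", config$nLayers), readout = NULL)

  ro <- params$readout
  dz <- dYhat * cache$yhat * (1 - cache$yhat)
  dzad <- matrix(dz, n, 1L) %*% t(ro$R2)
  dza <- if (is.null(cache$mask3)) dzad else dzad * cache$mask3
  dz1 <- dza * .lreluGrad(cache$z1)
  grads$readout <- list(
    R1 = crossprod(cache$Hfinal, dz1), r1 = colSums(dz1),
    R2 = crossprod(cache$zad, matrix(dz, n, 1L)), r2 = sum(dz))
  dH <- dz1 %*% t(ro$R1)

  dE <- if (m) matrix(0, m, config$dEdge) else
    matrix(0, 0L, config$dEdge)

  for (l in rev(seq_len(config$nLayers))) {
    p <- params$layers[[l]]
    cc <- cache$layers[[l]]
    g <- list()

    # edge stream backward (E_{l+1} = LN(E_l + MLP(E_l + (H_s+H_t) P)))
    if (m) {
      lnb <- .layerNormBackward(dE, cc$lnE, p$g2)
      g$g2 <- lnb$dgamma; g$be2 <- lnb$dbeta
      dRe <- lnb$dx
      dEl <- dRe
      dEout <- dRe
      g$E2 <- crossprod(cc$eactd, dEout)
      g$f2 <- colSums(dEout)
      deactd <- dEout %*% t(p$E2)
      deact <- if (is.null(cc$mask2)) deactd else deactd * cc$mask2
      dehid <- deact * .lreluGrad(cc$ehid)
      g$E1 <- crossprod(cc$Pin, dehid)
      g$f1 <- colSums(dehid)
      dPin <- dehid %*% t(p$E1)
      dEl <- dEl + dPin
      g$P <- crossprod(cc$Ssum, dPin)
      dSsum <- dPin %*% t(p$P)
      dHedge <- matrix(0, n, d)
      dHedge <- .indexAdd(dHedge, s, dSsum)
      dHedge <- .indexAdd(dHedge, t., dSsum)
    } else {
      dEl <- dE
      dHedge <- matrix(0, n, d)
      g$g2 <- p$g2 * 0; g$be2 <- p$be2 * 0
      g$E1 <- p$E1 * 0; g$f1 <- p$f1 * 0
      g$E2 <- p$E2 * 0; g$f2 <- p$f2 * 0
      g$P <- p$P * 0
    }

    # node stream backward (H_{l+1} = LN(H_l + MLP(H_l + attention)))
    lnb <- .layerNormBackward(dH, cc$lnN, p$g1)
    g$g1 <- lnb$dgamma; g$be1 <- lnb$dbeta
    dRn <- lnb$dx
    dHl <- dRn + dHedge
    dMlpOut <- dRn
    g$M2 <- crossprod(cc$actd, dMlpOut)
    g$c2 <- colSums(dMlpOut)
    dactd <- dMlpOut %*% t(p$M2)
    dact <- if (is.null(cc$mask1)) dactd else dactd * cc$mask1
    dhid <- dact * .lreluGrad(cc$hid)
    g$M1 <- crossprod(cc$U, dhid)
    g$c1 <- colSums(dhid)
    dU <- dhid %*% t(p$M1)
    dHl <- dHl + dU
    dAttnOut <- dU
    g$Wo <- crossprod(cc$O, dAttnOut)
    g$bO <- colSums(dAttnOut)
    dO <- dAttnOut %*% t(p$Wo)

    dQ <- matrix(0, n, H * dk)
    dK <- matrix(0, n, H * dk)
    dV <- matrix(0, n, d)
    g$wE <- p$wE * 0
    g$bSelf <- numeric(H)
    for (h in seq_len(H)) {
      ck <- ((h - 1L) * dk + 1L):(h * dk)
      cv <- ((h - 1L) * dv + 1L):(h * dv)
      a <- cc$alphas[[h]]
      dOh <- dO[, cv, drop = FALSE]
      dA <- tcrossprod(dOh, cc$V[, cv, drop = FALSE])
      dV[, cv] <- crossprod(a, dOh)
      dlog <- a * (dA - rowSums(dA * a))
      dQ[, ck] <- dlog %*% cc$K[, ck, drop = FALSE] / sqrt(dk)
      dK[, ck] <- crossprod(dlog, cc$Q[, ck, drop = FALSE]) / sqrt(dk)
      if (m) {
        dbvec <- dlog[cbind(s, t.)] + dlog[cbind(t., s)]
        g$wE[, h] <- crossprod(cc$El, dbvec)
        dEl <- dEl + outer(dbvec, p$wE[, h])
      }
      g$bSelf[h] <- sum(diag(dlog))
    }
    g$Wq <- crossprod(cc$Hl, dQ)
    g$Wk <- crossprod(cc$Hl, dK)
    g$Wv <- crossprod(cc$Hl, dV)
    dHl <- dHl + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)

    grads$layers[[l]] <- g[names(p)]
    dH <- dHl
    dE <- dEl
  }

  bN <- .embedBackward(params$nodeEmbed, cache$embN, dH)
  grads$nodeEmbed <- bN$grad
  bE <- .embedBackward(params$edgeEmbed, cache$embE, dE)
  grads$edgeEmbed <- bE$grad
  grads
}

#' Predict node scores for one subgraph
#'
#' Runs the full forward pass (embedding, \code{nLayers} attention layers,
#' sigmoid readout) in evaluation mode (no dropout, deterministic).
#'
#' @param checkpoint A checkpoint list as produced by [trainModel()] or
#'   [loadCheckpoint()].
#' @param sub An induced-subgraph list (see [sampleSubgraphs()]).
#' @return Named numeric vector of per-node quality scores in [0, 1].
#' @export
predictSubgraph <- function(checkpoint, sub) {
  .checkFeatureCompatibility(checkpoint, sub)
  fw <- .forwardSubgraph(checkpoint$params, checkpoint$config, sub,
                         train = FALSE, keepCache = FALSE)
  setNames(fw$yhat, sub$ids)
}

.checkFeatureCompatibility <- function(checkpoint, sub) {
  if (!identical(checkpoint$nodeFeatureNames,
                 colnames(sub$nodeFeatures)))
    stop("checkpoint/node feature mismatch: checkpoint expects [",
         paste(checkpoint$nodeFeatureNames, collapse = ", "),
         "] but subgraph provides [",
         paste(colnames(sub$nodeFeatures), collapse = ", "), "]")
  if (!identical(checkpoint$edgeFeatureNames,
                 colnames(sub$edgeFeatures)))
    stop("checkpoint/edge feature mismatch")
  invisible(TRUE)
}
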