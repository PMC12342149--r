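# Low-level neural-network primitives: leaky ReLU, row-wise layer
# normalization, masked softmax, Glorot initialization, and a recursive
# walker over nested parameter lists. Forward and backward passes are
# written out explicitly; the finite-difference gradient check in the test
# suite is the oracle for all of them.

.LRELU_SLOPE <- 0.01
.LN_EPS <- 1e-5

.lrelu <- function(x) pmax(x, 0) + .LRELU_SLOPE * pmin(x, 0)
.lreluGrad <- function(x) (x > 0) + .LRELU_SLOPE * (x <= 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Add a length-ncol vector to every row (fast replacement for sweep).
.addRowVec <- function(x, v) x + rep(v, each = nrow(x))
.mulRowVec <- function(x, v) x * rep(v, each = nrow(x))

# Row-wise layer normalization with learned scale/shift.
.layerNormForward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  list(y = .addRowVec(.mulRowVec(xhat, gamma), beta),
       xhat = xhat, inv = inv)
}

.layerNormBackward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- .mulRowVec(dy, gamma)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Row softmax over finite entries; -Inf logits get probability exactly 0.
.maskedSoftmax <- function(logits) {
  n <- nrow(logits)
  mx <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  e <- exp(logits - mx)
  e / rowSums(e)
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# Apply a function elementwise over parallel nested lists of numeric
# arrays, preserving structure.
.mapParams <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- .mapParams(f, a[[i]],
                             if (is.null(b)) NULL else b[[i]],
                             if (is.null(c)) NULL else c[[i]])
    out
  } else if (is.null(b)) f(a) else if (is.null(c)) f(a, b) else f(a, b, c)
}

.zerosLike <- function(params) .mapParams(function(p) p * 0, params)

.flattenParams <- function(params) unlist(params, use.names = FALSE)

.relistParams <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(node) {
    if (is.list(node)) return(lapply(node, fill))
    k <- length(node)
    out <- flat[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (!is.null(dim(node))) dim(out) <- dim(node)
    out
  }
  fill(skeleton)
}

# Sum rows of `m` into `acc` at positions `idx` (repeats accumulate).
.indexAdd <- function(acc, idx, m) {
  s <- rowsum(m, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  acc[rows, ] <- acc[rows, , drop = FALSE] + s
  acc
}
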