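# Reverse-mode automatic differentiation on a flat tape.
#
# Every network in the package (ZINB denoising autoencoder, GCN graph
# autoencoder, attention fusion, DEC head) is expressed in the primitives
# below. Nodes are environments holding a dense matrix `val`, an accumulated
# `grad`, and a `backfn` that pushes the node's gradient into its parents.
# The tape records creation order; backward() walks it in reverse. Gradients
# are validated against central finite differences in the test suite.

newTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tpNode <- function(tape, val, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

# leaf holding data or trainable parameters; grads accumulate here
tpLeaf <- function(tape, val) tpNode(tape, val)

tpAccum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

tpBackward <- function(tape, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

## ---- arithmetic primitives -------------------------------------------------

# A %*% B, optionally A %*% t(B)
tpMatmul <- function(tape, a, b, transB = FALSE) {
  val <- if (transB) tcrossprod(a$val, b$val) else a$val %*% b$val
  tpNode(tape, val, function(nd) {
    g <- nd$grad
    if (transB) {
      tpAccum(a, g %*% b$val)
      tpAccum(b, crossprod(g, a$val))
    } else {
      tpAccum(a, tcrossprod(g, b$val))
      tpAccum(b, crossprod(a$val, g))
    }
  })
}

# elementwise sum; `b` may be a 1 x d row (bias) broadcast over rows of `a`
tpAdd <- function(tape, a, b) {
  bias <- is.matrix(b$val) && nrow(b$val) == 1L && nrow(a$val) > 1L
  val <- if (bias) sweep(a$val, 2L, b$val[1L, ], "+") else a$val + b$val
  tpNode(tape, val, function(nd) {
    g <- nd$grad
    tpAccum(a, g)
    tpAccum(b, if (bias) matrix(colSums(g), 1L) else g)
  })
}

tpSub <- function(tape, a, b) {
  tpNode(tape, a$val - b$val, function(nd) {
    tpAccum(a, nd$grad)
    tpAccum(b, -nd$grad)
  })
}

tpMul <- function(tape, a, b) {
  tpNode(tape, a$val * b$val, function(nd) {
    tpAccum(a, nd$grad * b$val)
    tpAccum(b, nd$grad * a$val)
  })
}

tpDiv <- function(tape, a, b) {
  val <- a$val / b$val
  tpNode(tape, val, function(nd) {
    tpAccum(a, nd$grad / b$val)
    tpAccum(b, -nd$grad * val / b$val)
  })
}

# x * k and x + k for a plain numeric constant k (scalar or conformable array)
tpScale <- function(tape, a, k) {
  tpNode(tape, a$val * k, function(nd) tpAccum(a, nd$grad * k))
}

tpShift <- function(tape, a, k) {
  tpNode(tape, a$val + k, function(nd) tpAccum(a, nd$grad))
}

# multiply row i by constant scalar v[i] (size-factor scaling)
tpRowScale <- function(tape, a, v) {
  stopifnot(length(v) == nrow(a$val))
  tpNode(tape, a$val * v, function(nd) tpAccum(a, nd$grad * v))
}

## ---- nonlinearities --------------------------------------------------------

tpExp <- function(tape, a) {
  val <- exp(a$val)
  tpNode(tape, val, function(nd) tpAccum(a, nd$grad * val))
}

tpLog <- function(tape, a) {
  tpNode(tape, log(a$val), function(nd) tpAccum(a, nd$grad / a$val))
}

tpTanh <- function(tape, a) {
  val <- tanh(a$val)
  tpNode(tape, val, function(nd) tpAccum(a, nd$grad * (1 - val^2)))
}

tpSigmoid <- function(tape, a) {
  val <- 1 / (1 + exp(-a$val))
  tpNode(tape, val, function(nd) tpAccum(a, nd$grad * val * (1 - val)))
}

tpRelu <- function(tape, a) {
  pos <- a$val > 0
  tpNode(tape, a$val * pos, function(nd) tpAccum(a, nd$grad * pos))
}

tpLgamma <- function(tape, a) {
  tpNode(tape, lgamma(a$val), function(nd) tpAccum(a, nd$grad * digamma(a$val)))
}

# hard clamp; gradient is zero outside [lo, hi] (saturated region)
tpClamp <- function(tape, a, lo, hi) {
  inside <- a$val >= lo & a$val <= hi
  tpNode(tape, pmin(pmax(a$val, lo), hi),
         function(nd) tpAccum(a, nd$grad * inside))
}

## ---- row-structured ops ----------------------------------------------------

tpSoftmaxRows <- function(tape, a) {
  m <- a$val - apply(a$val, 1L, max)
  e <- exp(m)
  val <- e / rowSums(e)
  tpNode(tape, val, function(nd) {
    g <- nd$grad
    tpAccum(a, (g - rowSums(g * val)) * val)
  })
}

# normalize rows to sum 1 (no exponential)
tpRowNorm <- function(tape, a) {
  s <- rowSums(a$val)
  val <- a$val / s
  tpNode(tape, val, function(nd) {
    g <- nd$grad
    tpAccum(a, (g - rowSums(g * val)) / s)
  })
}

tpRowSums <- function(tape, a) {
  nc <- ncol(a$val)
  tpNode(tape, matrix(rowSums(a$val), ncol = 1L), function(nd) {
    tpAccum(a, matrix(nd$grad, nrow(a$val), nc))
  })
}

# outer sum of a column vector (n x 1) and a row layout of b (k x 1): n x k
tpOuterAdd <- function(tape, a, b) {
  val <- outer(a$val[, 1L], b$val[, 1L], "+")
  tpNode(tape, val, function(nd) {
    tpAccum(a, matrix(rowSums(nd$grad), ncol = 1L))
    tpAccum(b, matrix(colSums(nd$grad), ncol = 1L))
  })
}

tpCbind <- function(tape, nodes) {
  val <- do.call(cbind, lapply(nodes, function(x) x$val))
  widths <- vapply(nodes, function(x) ncol(x$val), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tpNode(tape, val, function(nd) {
    for (i in seq_along(nodes)) {
      tpAccum(nodes[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

## ---- reductions ------------------------------------------------------------

tpSum <- function(tape, a) {
  dims <- dim(a$val)
  tpNode(tape, matrix(sum(a$val), 1L, 1L), function(nd) {
    tpAccum(a, matrix(nd$grad[1L], dims[1L], dims[2L]))
  })
}

tpMean <- function(tape, a) {
  dims <- dim(a$val)
  n <- length(a$val)
  tpNode(tape, matrix(mean(a$val), 1L, 1L), function(nd) {
    tpAccum(a, matrix(nd$grad[1L] / n, dims[1L], dims[2L]))
  })
}

## ---- optimizer -------------------------------------------------------------

# Adam with global L2 gradient-norm clipping. `params` and `grads` are named
# lists of matrices; state persists across steps in `st`.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clipNorm = 3) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(clipNorm) && total > clipNorm) {
    grads <- lapply(grads, function(g) g * (clipNorm / total))
  }
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Glorot-uniform initialization for a din x dout weight matrix
glorot <- function(din, dout) {
  r <- sqrt(6 / (din + dout))
  matrix(stats::runif(din * dout, -r, r), din, dout)
}

## ---- fused composite ops ---------------------------------------------------
## Single tape nodes with analytic backward passes for the hot paths, so one
## training step does not allocate long chains of large intermediates. Each
## is checked against central finite differences in the test suite.

# one dot-product attention head: out = softmax(Q K^T [/ sqrt(dk)]) V;
# forward and backward run in compiled code (src/ops.cpp)
tpAttentionHead <- function(tape, Q, K, V, scaled = FALSE) {
  fwd <- .attnHeadForward(Q$val, K$val, V$val, scaled)
  tpNode(tape, fwd$out, function(nd) {
    bk <- .attnHeadBackward(fwd$a, Q$val, K$val, V$val, nd$grad, scaled)
    tpAccum(Q, bk$gQ)
    tpAccum(K, bk$gK)
    tpAccum(V, bk$gV)
  })
}

# mean squared error between A and sigmoid(Z Z^T)
tpGraphReconMSE <- function(tape, Z, A) {
  At <- 1 / (1 + exp(-tcrossprod(Z$val)))
  diffA <- A - At
  n2 <- length(A)
  tpNode(tape, matrix(mean(diffA^2), 1L, 1L), function(nd) {
    G <- (-2 / n2 * nd$grad[1L]) * diffA * At * (1 - At)
    tpAccum(Z, (G + t(G)) %*% Z$val)
  })
}

# mean ZINB negative log-likelihood of Xp under (pi, mu, theta); `mask`
# marks the entries treated as zeros (decided on the original counts)
tpZinbLoss <- function(tape, Xp, mask, piN, muN, thN, eps = 1e-10) {
  p <- piN$val; mu <- muN$val; th <- thN$val
  n <- length(Xp)
  r <- th / (th + mu)
  logr <- log(r)
  nb0 <- exp(th * logr)
  p0 <- p + (1 - p) * nb0 + eps
  llZero <- log(p0)
  llPos <- log(1 - p + eps) + lgamma(Xp + th) - lgamma(th) - lgamma(Xp + 1) +
    th * logr + Xp * log(mu / (th + mu))
  val <- -sum(mask * llZero + (1 - mask) * llPos) / n
  tpNode(tape, matrix(val, 1L, 1L), function(nd) {
    s <- -nd$grad[1L] / n
    # zero-entry branch
    gPi0 <- (1 - nb0) / p0
    gTh0 <- (1 - p) * nb0 * (logr + mu / (th + mu)) / p0
    gMu0 <- -(1 - p) * nb0 * th / ((th + mu) * p0)
    # positive-entry branch
    gPi1 <- -1 / (1 - p + eps)
    gTh1 <- digamma(Xp + th) - digamma(th) + logr + (mu - Xp) / (th + mu)
    gMu1 <- Xp / mu - (Xp + th) / (mu + th)
    tpAccum(piN, s * (mask * gPi0 + (1 - mask) * gPi1))
    tpAccum(thN, s * (mask * gTh0 + (1 - mask) * gTh1))
    tpAccum(muN, s * (mask * gMu0 + (1 - mask) * gMu1))
  })
}

# Student's-t soft assignment Q from embedding Z and centroids C
tpStudentQ <- function(tape, Z, C, alpha = 1) {
  d2 <- outer(rowSums(Z$val^2), rowSums(C$val^2), "+") -
    2 * tcrossprod(Z$val, C$val)
  d2[d2 < 0] <- 0
  nr <- nrow(qun <- 1 / (1 + d2 / alpha)); nc <- ncol(qun)
  srow <- .rowSums(qun, nr, nc)
  Q <- qun / srow
  tpNode(tape, Q, function(nd) {
    g <- nd$grad
    gqun <- (g - .rowSums(g * Q, nr, nc)) / srow
    gd2 <- -gqun * qun^2 / alpha
    tpAccum(Z, 2 * (rowSums(gd2) * Z$val - gd2 %*% C$val))
    tpAccum(C, 2 * (colSums(gd2) * C$val - crossprod(gd2, Z$val)))
  })
}
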