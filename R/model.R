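## The fused network: a ZINB denoising autoencoder and a GCN graph
## autoencoder whose layerwise embeddings are combined by two multi-head
## attention blocks. Built on the autodiff tape in tape.R. All widths follow
## the fixed hidden architecture 256-64-16-64-256; the two fusion blocks act
## at the 256- and 64-wide encoder levels, and the second fused output R2 is
## the clustering representation.

modelDims <- c(256L, 64L, 16L)

# constant (non-trainable) sparse propagation wrapper: S is a plain or
# Matrix-package sparse matrix; only `b` receives gradient. S must be
# symmetric (true for the normalized adjacency).
tpPropagate <- function(tape, S, b) {
  val <- as.matrix(S %*% b$val)
  tpNode(tape, val, function(nd) tpAccum(b, as.matrix(S %*% nd$grad)))
}

initFusionParams <- function(prefix, dim, nHeads) {
  dh <- dim %/% nHeads
  p <- list()
  for (m in seq_len(nHeads)) {
    p[[sprintf("%s.q%d", prefix, m)]] <- glorot(dim, dh)
    p[[sprintf("%s.k%d", prefix, m)]] <- glorot(dim, dh)
    p[[sprintf("%s.v%d", prefix, m)]] <- glorot(dim, dh)
  }
  p[[sprintf("%s.o", prefix)]] <- glorot(dim, dim)
  p
}

# allocate all trainable parameters for input width m under the given
# ablation switches; seeded by the caller
initModelParams <- function(m, cfg) {
  d <- modelDims
  p <- list()
  useDAE <- !cfg$noDAE
  useGAE <- !cfg$noGAE
  if (useDAE) {
    p$Ws <- glorot(m, d[1])                     # (shared) reduction layer
    p$b1 <- matrix(0, 1, d[1])
    p$W2 <- glorot(d[1], d[2]); p$b2 <- matrix(0, 1, d[2])
    p$W3 <- glorot(d[2], d[3]); p$b3 <- matrix(0, 1, d[3])
    p$Wd1 <- glorot(d[3], d[2]); p$bd1 <- matrix(0, 1, d[2])
    p$Wd2 <- glorot(d[2], d[1]); p$bd2 <- matrix(0, 1, d[1])
    p$Wpi <- glorot(d[1], m); p$bpi <- matrix(0, 1, m)
    p$Wmu <- glorot(d[1], m); p$bmu <- matrix(0, 1, m)
    p$Wth <- glorot(d[1], m); p$bth <- matrix(0, 1, m)
  }
  if (useGAE) {
    if (!cfg$shareReduction || !useDAE) p$Wg1 <- glorot(m, d[1])
    p$Wg2 <- glorot(d[1], d[2])
    p$Wg3 <- glorot(d[2], d[3])
  }
  if (cfg$noAttention) {
    p$Wm1 <- glorot(2L * d[1], d[1]); p$bm1 <- matrix(0, 1, d[1])
    p$Wm2 <- glorot(2L * d[2], d[2]); p$bm2 <- matrix(0, 1, d[2])
  } else {
    p <- c(p, initFusionParams("f1", d[1], cfg$nHeads),
           initFusionParams("f2", d[2], cfg$nHeads))
  }
  p
}

# one attention fusion block on the tape; Zl supplies queries, El keys,
# values and the residual
tapeFusionBlock <- function(tape, P, prefix, Zl, El, nHeads, scaled) {
  heads <- vector("list", nHeads)
  for (m in seq_len(nHeads)) {
    Q <- tpMatmul(tape, Zl, P[[sprintf("%s.q%d", prefix, m)]])
    K <- tpMatmul(tape, El, P[[sprintf("%s.k%d", prefix, m)]])
    V <- tpMatmul(tape, El, P[[sprintf("%s.v%d", prefix, m)]])
    heads[[m]] <- tpAttentionHead(tape, Q, K, V, scaled = scaled)
  }
  conc <- tpCbind(tape, heads)
  tpAdd(tape, tpMatmul(tape, conc, P[[sprintf("%s.o", prefix)]]), El)
}

# MLP stand-in for a fusion block (the "without attention" ablation)
tapeMlpFuse <- function(tape, P, W, b, Zl, El) {
  conc <- tpCbind(tape, list(Zl, El))
  tpRelu(tape, tpAdd(tape, tpMatmul(tape, conc, P[[W]]), P[[b]]))
}

# Full forward pass. `params` is the named list of parameter matrices;
# `data` carries the constant inputs; returns tape nodes for the losses and
# embeddings plus the leaf nodes (for gradient collection).
modelForward <- function(params, data, cfg, noiseOn = FALSE,
                         centroids = NULL, Pconst = NULL) {
  tape <- newTape()
  P <- lapply(params, function(w) tpLeaf(tape, w))
  useDAE <- !cfg$noDAE
  useGAE <- !cfg$noGAE

  Xb <- tpLeaf(tape, data$Xbar)
  Xin <- if (noiseOn && useDAE) {
    tpLeaf(tape, data$Xbar +
             matrix(stats::rnorm(length(data$Xbar), 0, cfg$noiseSD),
                    nrow(data$Xbar)))
  } else Xb

  out <- list(tape = tape, leaves = P)

  # --- GCN encoder over the normalized adjacency ---
  if (useGAE) {
    Wg1 <- if (cfg$shareReduction && useDAE) P$Ws else P$Wg1
    Z1 <- tpTanh(tape, tpPropagate(tape, data$Ahat, tpMatmul(tape, Xb, Wg1)))
    Z2 <- tpTanh(tape, tpPropagate(tape, data$Ahat, tpMatmul(tape, Z1, P$Wg2)))
    Z3 <- tpTanh(tape, tpPropagate(tape, data$Ahat, tpMatmul(tape, Z2, P$Wg3)))
    out$lGraph <- tpGraphReconMSE(tape, Z3, data$Asym)
    out$Z1 <- Z1; out$Z2 <- Z2; out$Z3 <- Z3
  }

  # --- DAE encoder with fusion interleaved ---
  if (useDAE) {
    E1 <- tpRelu(tape, tpAdd(tape, tpMatmul(tape, Xin, P$Ws), P$b1))
    Q1src <- if (useGAE) out$Z1 else E1
    R1 <- if (cfg$noAttention) {
      tapeMlpFuse(tape, P, "Wm1", "bm1", Q1src, E1)
    } else {
      tapeFusionBlock(tape, P, "f1", Q1src, E1, cfg$nHeads, cfg$scaledAttention)
    }
    E2 <- tpRelu(tape, tpAdd(tape, tpMatmul(tape, R1, P$W2), P$b2))
    Q2src <- if (useGAE) out$Z2 else E2
    R2 <- if (cfg$noAttention) {
      tapeMlpFuse(tape, P, "Wm2", "bm2", Q2src, E2)
    } else {
      tapeFusionBlock(tape, P, "f2", Q2src, E2, cfg$nHeads, cfg$scaledAttention)
    }
    H <- tpAdd(tape, tpMatmul(tape, R2, P$W3), P$b3)
    D1 <- tpRelu(tape, tpAdd(tape, tpMatmul(tape, H, P$Wd1), P$bd1))
    D <- tpRelu(tape, tpAdd(tape, tpMatmul(tape, D1, P$Wd2), P$bd2))

    piN <- tpSigmoid(tape, tpAdd(tape, tpMatmul(tape, D, P$Wpi), P$bpi))
    muN <- tpRowScale(tape,
                      tpExp(tape, tpClamp(tape,
                                          tpAdd(tape, tpMatmul(tape, D, P$Wmu), P$bmu),
                                          -15, 15)),
                      data$sizeFactors)
    thN <- tpClamp(tape,
                   tpExp(tape, tpClamp(tape,
                                       tpAdd(tape, tpMatmul(tape, D, P$Wth), P$bth),
                                       -15, 15)),
                   1e-4, 1e4)
    out$E1 <- E1; out$E2 <- E2; out$R1 <- R1; out$R2 <- R2; out$H <- H
    out$pi <- piN; out$mu <- muN; out$theta <- thN
    out$lZinb <- tpZinbLoss(tape, data$Xprime, data$zeroMask, piN, muN, thN,
                            eps = cfg$zinbEps)
  } else {
    # without the DAE the attention fuses the GAE embedding with itself and
    # the clustering feature comes from the topological path alone
    R1 <- if (cfg$noAttention) {
      tapeMlpFuse(tape, P, "Wm1", "bm1", out$Z1, out$Z1)
    } else {
      tapeFusionBlock(tape, P, "f1", out$Z1, out$Z1, cfg$nHeads, cfg$scaledAttention)
    }
    R2 <- if (cfg$noAttention) {
      tapeMlpFuse(tape, P, "Wm2", "bm2", out$Z2, out$Z2)
    } else {
      tapeFusionBlock(tape, P, "f2", out$Z2, out$Z2, cfg$nHeads, cfg$scaledAttention)
    }
    out$R1 <- R1; out$R2 <- R2
  }

  # --- pretraining loss: L_train = L_zinb + r1 * L_graph ---
  lTrain <- NULL
  if (!is.null(out$lZinb)) lTrain <- out$lZinb
  if (!is.null(out$lGraph)) {
    g <- tpScale(tape, out$lGraph, cfg$r1)
    lTrain <- if (is.null(lTrain)) g else tpAdd(tape, lTrain, g)
  }
  out$lTrain <- lTrain

  # --- DEC head (fine-tuning) ---
  if (!is.null(centroids)) {
    Cn <- tpLeaf(tape, centroids)
    out$centroidLeaf <- Cn
    Qn <- tpStudentQ(tape, out$R2, Cn, alpha = cfg$alpha)
    out$Q <- Qn
    if (!is.null(Pconst)) {
      logQ <- tpLog(tape, tpShift(tape, Qn, 1e-12))
      crossEnt <- tpSum(tape, tpMul(tape, tpLeaf(tape, Pconst), logQ))
      ent <- sum(Pconst * log(pmax(Pconst, 1e-12)))
      out$lKL <- tpShift(tape, tpScale(tape, crossEnt, -1), ent)
      total <- out$lKL
      if (!is.null(out$lTrain)) {
        total <- tpAdd(tape, total, tpScale(tape, out$lTrain, cfg$r2))
      }
      out$loss <- total
    }
  }
  out
}
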