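# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (explicit loops, factorial forms) so they do
# not share code paths with the package.

# NB pmf at integer x via the factorial form (no lgamma shortcuts shared
# with nbLogPmf beyond base gamma itself)
oracleNbPmf <- function(x, mu, theta) {
  (gamma(x + theta) / (gamma(x + 1) * gamma(theta))) *
    (theta / (theta + mu))^theta * (mu / (theta + mu))^x
}

oracleZinbNll <- function(x, p, mu, theta) {
  lik <- if (x == 0) p + (1 - p) * oracleNbPmf(0, mu, theta) else
    (1 - p) * oracleNbPmf(x, mu, theta)
  -log(lik)
}

# pair-counting ARI over all cell pairs
oracleARI <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sameT <- truth[i] == truth[j]
    sameP <- pred[i] == pred[j]
    if (sameT && sameP) a <- a + 1
    else if (sameT && !sameP) b <- b + 1
    else if (!sameT && sameP) c <- c + 1
    else d <- d + 1
  }
  tot <- a + b + c + d
  expected <- (a + b) * (a + c) / tot
  maxIdx <- ((a + b) + (a + c)) / 2
  if (maxIdx == expected) return(1)
  (a - expected) / (maxIdx - expected)
}

# entropy/MI through an explicit double loop over the contingency table
oracleNMI <- function(truth, pred) {
  n <- length(truth)
  tu <- unique(truth); pu <- unique(pred)
  hT <- 0
  for (t in tu) { p <- sum(truth == t) / n; hT <- hT - p * log(p) }
  hP <- 0
  for (q in pu) { p <- sum(pred == q) / n; hP <- hP - p * log(p) }
  if (hT == 0 && hP == 0) return(1)
  if (hT == 0 || hP == 0) return(0)
  mi <- 0
  for (t in tu) for (q in pu) {
    pij <- sum(truth == t & pred == q) / n
    if (pij > 0) mi <- mi + pij * log(pij / ((sum(truth == t) / n) * (sum(pred == q) / n)))
  }
  mi / sqrt(hT * hP)
}

# O(n^2) silhouette with explicit per-cell loops
oracleSilhouette <- function(Z, labels) {
  n <- nrow(Z)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(Z) - Z[i, ])^2))
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- Inf
    for (l in unique(labels[!own])) b <- min(b, mean(di[labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# central finite-difference gradient of f with respect to the matrix w
numericalGrad <- function(f, w, h = 1e-5) {
  g <- w * 0
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    g[i] <- (f(wp) - f(wm)) / (2 * h)
  }
  g
}

# tiny preprocessed object + data list for model-level tests
makeTinyData <- function(nCells = 30, nGenes = 20, k = 2, seed = 42) {
  sce <- simulateCounts(nCells = nCells, nGenes = nGenes, kClusters = k,
                        markersPerCluster = 4, seed = seed)
  prep <- preprocessCounts(scFuseClust:::asCellMatrix(sce), k = 5)
  cfg <- scfConfig(seed = seed)
  data <- list(
    Xbar = prep@Xbar,
    Ahat = Matrix::Matrix(prep@graph$Ahat, sparse = TRUE),
    Asym = prep@graph$Asym,
    sizeFactors = prep@sizeFactors,
    Xprime = tailorTransform(prep@X, cfg$tailorRate, cfg$lossRate),
    zeroMask = (prep@X == 0) * 1
  )
  list(sce = sce, prep = prep, cfg = cfg, data = data,
       labels = sce$cluster)
}
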