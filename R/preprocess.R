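## Preprocessing: filtering, HVG selection and ordering, normalization,
## and the cell-cell KNN graph.

# Coerce supported inputs to a dense cells x genes matrix. The package works
# in the cells-in-rows orientation internally; SingleCellExperiment (genes in
# rows) is transposed on the way in.
asCellMatrix <- function(x) {
  if (methods::is(x, "SingleCellExperiment") ||
      methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, "counts")
    return(t(as.matrix(x)))
  }
  if (methods::is(x, "Matrix")) x <- as.matrix(x)
  stopifnot(is.matrix(x))
  x
}

#' Drop cells and genes with zero total counts
#'
#' @param x cells-by-genes count matrix or a `SingleCellExperiment`.
#' @return dense cells-by-genes matrix with every row and column total > 0.
#' @export
filterEmpty <- function(x) {
  X <- asCellMatrix(x)
  if (any(X < 0)) stop("counts must be non-negative")
  keepCells <- rowSums(X) > 0
  keepGenes <- colSums(X) > 0
  X <- X[keepCells, keepGenes, drop = FALSE]
  if (nrow(X) == 0L || ncol(X) == 0L) stop("no cells or genes left after filtering")
  X
}

# per-gene normalized dispersion score (mean-binned), the classic
# dispersion-based HVG statistic computed on log-normalized expression
hvgDispersionScore <- function(Xnorm, nBins = 20L) {
  mu <- colMeans(Xnorm)
  v <- apply(Xnorm, 2L, stats::var)
  disp <- v / pmax(mu, 1e-12)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1L))),
              include.lowest = TRUE)
  score <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) >= 2L) {
      m <- mean(disp[idx])
      s <- stats::sd(disp[idx])
      score[idx] <- if (is.finite(s) && s > 0) (disp[idx] - m) / s else 0
    } else if (length(idx) == 1L) {
      score[idx] <- 0
    }
  }
  score
}

# Seurat-v3-flavoured alternative: variance of clipped standardized counts
hvgVstScore <- function(X) {
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  ok <- v > 0 & mu > 0
  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3)
  expSd <- sqrt(10^stats::predict(fit, log10(pmax(mu, 1e-12))))
  expSd[!is.finite(expSd) | expSd <= 0] <- Inf
  n <- nrow(X)
  clipMax <- sqrt(n)
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, expSd, "/")
  Z <- pmin(Z, clipMax)
  apply(Z, 2L, function(z) sum(z^2) / (n - 1))
}

#' Select highly variable genes and order them by expression magnitude
#'
#' Scores genes with a standard highly-variable-gene criterion, keeps the top
#' `nHVG`, then orders the selection by total raw counts in descending order.
#' The descending order is a contract the re-weighted ZINB loss relies on:
#' after [tailorTransform()] the trailing `(1 - tailorRate)` fraction of
#' columns — the lowest-expression HVGs — are the ones whose loss
#' contribution is magnified.
#'
#' @param x cells-by-genes count matrix or `SingleCellExperiment`.
#' @param nHVG number of genes to keep (default 2500).
#' @param flavor `"dispersion"` (mean-binned normalized dispersion on
#'   log-normalized data) or `"vst"` (variance of clipped standardized
#'   counts).
#' @return integer vector of `nHVG` column indices into `x`, ordered by
#'   decreasing total expression.
#' @export
selectOrderHVGs <- function(x, nHVG = 2500, flavor = c("dispersion", "vst")) {
  flavor <- match.arg(flavor)
  X <- asCellMatrix(x)
  if (nHVG > ncol(X)) stop("nHVG exceeds the number of genes")
  score <- if (flavor == "dispersion") {
    hvgDispersionScore(normalizeCounts(X)$Xnorm)
  } else {
    hvgVstScore(X)
  }
  sel <- order(score, decreasing = TRUE)[seq_len(nHVG)]
  sel[order(colSums(X)[sel], decreasing = TRUE)]
}

#' Library-size normalize, log-transform, and z-score
#'
#' Each cell is scaled to a common library size (`targetSum`, by default the
#' median library), log1p-transformed (`Xnorm`), then each gene is centred
#' and scaled to unit variance (`Xbar`). Genes with (near-)zero variance get
#' an epsilon-guarded denominator and come out as zeros.
#'
#' @param x cells-by-genes count matrix or `SingleCellExperiment`.
#' @param targetSum library size each cell is scaled to; `NULL` for the
#'   median library size.
#' @return list with `Xnorm`, `Xbar`, and `sizeFactors` (library size divided
#'   by its median, the per-cell factor the ZINB mean head is scaled by).
#' @export
normalizeCounts <- function(x, targetSum = NULL) {
  X <- asCellMatrix(x)
  lib <- rowSums(X)
  if (any(lib <= 0)) stop("cells with zero counts present; run filterEmpty()")
  if (is.null(targetSum)) targetSum <- stats::median(lib)
  Xnorm <- log1p(X / lib * targetSum)
  mu <- colMeans(Xnorm)
  sdv <- apply(Xnorm, 2L, stats::sd)
  zeroVar <- !is.finite(sdv) | sdv < 1e-12
  if (any(zeroVar)) {
    warning(sum(zeroVar), " gene(s) with zero variance; z-scores set to 0")
  }
  sdv[zeroVar] <- Inf
  Xbar <- sweep(sweep(Xnorm, 2L, mu, "-"), 2L, sdv, "/")
  list(Xnorm = Xnorm, Xbar = Xbar,
       sizeFactors = unname(lib / stats::median(lib)))
}

#' Build the k-nearest-neighbour cell graph
#'
#' For every cell, its `k` nearest neighbours under cosine distance receive a
#' directed edge weighted by a Gaussian kernel on the distance,
#' \eqn{\exp(-d^2 / (2\sigma^2))}. The bandwidth is local by default
#' (\eqn{\sigma_i} = distance to the k-th neighbour of cell i) or a single
#' global median distance. The directed adjacency is returned together with
#' its self-looped symmetrically normalized form from
#' [normalizeAdjacency()].
#'
#' @param Xnorm cells-by-genes normalized expression matrix.
#' @param k neighbours per cell (default 15).
#' @param sigmaMode `"local"` or `"median"` Gaussian bandwidth.
#' @param binarize drop kernel weights and use 0/1 edges.
#' @return list with directed weighted adjacency `A` (n x n), its max-
#'   symmetrized form `Asym`, and the propagation matrix `Ahat`.
#' @export
buildCellGraph <- function(Xnorm, k = 15, sigmaMode = c("local", "median"),
                           binarize = FALSE) {
  sigmaMode <- match.arg(sigmaMode)
  stopifnot(is.matrix(Xnorm))
  n <- nrow(Xnorm)
  if (k >= n) stop("k must be smaller than the number of cells")
  nrm <- sqrt(rowSums(Xnorm^2))
  nrm[nrm == 0] <- 1
  U <- Xnorm / nrm
  D <- 1 - tcrossprod(U)               # cosine distance
  D[D < 0] <- 0
  diag(D) <- Inf
  A <- matrix(0, n, n)
  kth <- numeric(n)
  nbrs <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[seq_len(k)]
    nbrs[i, ] <- ord
    kth[i] <- D[i, ord[k]]
  }
  sigma <- if (sigmaMode == "local") pmax(kth, 1e-12) else {
    rep(max(stats::median(D[cbind(rep(seq_len(n), each = k), as.integer(t(nbrs)))]),
            1e-12), n)
  }
  for (i in seq_len(n)) {
    d <- D[i, nbrs[i, ]]
    A[i, nbrs[i, ]] <- if (binarize) 1 else exp(-d^2 / (2 * sigma[i]^2))
  }
  Asym <- pmax(A, t(A))
  list(A = A, Asym = Asym, Ahat = normalizeAdjacency(A))
}

#' Self-looped symmetric normalization of an adjacency matrix
#'
#' Symmetrizes a (possibly directed) non-negative adjacency by the
#' elementwise maximum with its transpose, adds self-loops, and normalizes:
#' \eqn{\hat A = D^{-1/2}(A_{sym} + I)D^{-1/2}} with \eqn{D} the degree
#' matrix of \eqn{A_{sym} + I}. The result is symmetric with spectral radius
#' at most 1; self-loops guarantee positive degrees.
#'
#' @param A square non-negative adjacency matrix.
#' @return normalized propagation matrix of the same dimension.
#' @export
normalizeAdjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("adjacency must be non-negative")
  S <- pmax(A, t(A))
  diag(S) <- diag(S) + 1            # self-loops on top of any existing weight
  dInv <- 1 / sqrt(rowSums(S))
  S * outer(dInv, dInv)
}

#' Preprocessed single-cell data container
#'
#' Bundles everything the model consumes: the filtered raw counts restricted
#' to ordered highly variable genes (`X`), the log-normalized (`Xnorm`) and
#' gene-z-scored (`Xbar`) matrices, per-cell size factors, the selected gene
#' indices, and the cell graph (`A`, `Asym`, `Ahat`).
#'
#' @slot X raw counts, cells x selected genes, columns ordered by decreasing
#'   total expression.
#' @slot Xnorm log-normalized expression on the same genes.
#' @slot Xbar gene-wise z-scored expression on the same genes.
#' @slot sizeFactors per-cell library-size factors.
#' @slot selectedGenes integer indices of the kept genes in the input.
#' @slot graph list with `A`, `Asym`, `Ahat` from [buildCellGraph()].
#' @slot cellIds,geneIds identifiers carried from the input.
#' @export
setClass("ScfPreprocessed", representation(
  X = "matrix", Xnorm = "matrix", Xbar = "matrix",
  sizeFactors = "numeric", selectedGenes = "integer",
  graph = "list", cellIds = "character", geneIds = "character"
))

setValidity("ScfPreprocessed", function(object) {
  msg <- NULL
  if (!all(dim(object@X) == dim(object@Xbar))) msg <- c(msg, "X/Xbar shape mismatch")
  if (length(object@sizeFactors) != nrow(object@X)) {
    msg <- c(msg, "sizeFactors length must equal the number of cells")
  }
  if (!all(c("A", "Asym", "Ahat") %in% names(object@graph))) {
    msg <- c(msg, "graph must contain A, Asym, Ahat")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ScfPreprocessed compact description
#' @param object a `ScfPreprocessed`.
#' @export
setMethod("show", "ScfPreprocessed", function(object) {
  cat("ScfPreprocessed:", nrow(object@X), "cells x", ncol(object@X),
      "ordered HVGs; KNN graph with",
      sum(object@graph$A > 0), "directed edges\n")
})

#' Run the full preprocessing pipeline
#'
#' Filters empty cells/genes, selects and orders `nHVG` highly variable
#' genes, normalizes, and builds the cell graph.
#'
#' @param x cells-by-genes count matrix or `SingleCellExperiment`.
#' @param nHVG number of highly variable genes; `NULL` keeps
#'   `min(2500, #genes)`.
#' @param k KNN graph neighbours (default 15).
#' @param flavor HVG criterion, see [selectOrderHVGs()].
#' @param sigmaMode,binarize graph options, see [buildCellGraph()].
#' @param targetSum see [normalizeCounts()].
#' @return a [ScfPreprocessed-class] object.
#' @export
preprocessCounts <- function(x, nHVG = NULL, k = 15,
                             flavor = c("dispersion", "vst"),
                             sigmaMode = c("local", "median"),
                             binarize = FALSE, targetSum = NULL) {
  flavor <- match.arg(flavor)
  sigmaMode <- match.arg(sigmaMode)
  X0 <- asCellMatrix(x)
  X <- filterEmpty(X0)
  if (is.null(nHVG)) nHVG <- min(2500L, ncol(X))
  sel <- selectOrderHVGs(X, nHVG = nHVG, flavor = flavor)
  Xsel <- X[, sel, drop = FALSE]
  nrm <- normalizeCounts(Xsel, targetSum = targetSum)
  graph <- buildCellGraph(nrm$Xnorm, k = k, sigmaMode = sigmaMode,
                          binarize = binarize)
  methods::new("ScfPreprocessed",
               X = Xsel, Xnorm = nrm$Xnorm, Xbar = nrm$Xbar,
               sizeFactors = nrm$sizeFactors, selectedGenes = as.integer(sel),
               graph = graph,
               cellIds = if (!is.null(rownames(Xsel))) rownames(Xsel) else
                 sprintf("cell%04d", seq_len(nrow(Xsel))),
               geneIds = if (!is.null(colnames(Xsel))) colnames(Xsel) else
                 sprintf("gene%04d", sel))
}
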