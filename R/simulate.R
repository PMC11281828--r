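#' Simulate ZINB-distributed single-cell counts with known clusters
#'
#' Generates a cells-by-genes raw count matrix from a zero-inflated negative
#' binomial model with cluster-specific mean profiles. Each cluster receives
#' `markersPerCluster` marker genes whose mean is elevated by
#' `exp(logFC)`; a fraction `lowExprFraction` of those markers is placed at a
#' low absolute baseline, so that they are highly variable yet lowly
#' expressed — the regime the low-expression-weighted ZINB loss targets.
#' Every entry is a technical zero with probability `dropoutPi`, otherwise
#' NB(mu, theta).
#'
#' Baseline gene means are drawn log-normally and scaled by a per-cell
#' log-normal library-size factor (sdlog 0.15) around `meanScale`.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param kClusters number of ground-truth clusters.
#' @param meanScale average baseline expression level (mean of the gene-mean
#'   distribution). Default 1.
#' @param logFC natural-log fold change of marker genes over baseline.
#'   Default 2 (about 7.4-fold), a strong, well-separated marker signal.
#' @param markersPerCluster marker genes per cluster; must satisfy
#'   `markersPerCluster * kClusters <= nGenes`.
#' @param dispersion NB dispersion theta of every gene. Default 2.
#' @param dropoutPi zero-inflation probability in \[0, 1\]. Default 0.1.
#' @param lowExprFraction fraction of each cluster's markers given a low
#'   absolute baseline (meanScale / 10) before the fold change. Default 0.5.
#' @param clusterProps optional cluster mixing proportions (length
#'   `kClusters`, summing to 1); equal sizes when `NULL`. Set
#'   `dirichletAlpha` to draw them from a symmetric Dirichlet instead.
#' @param dirichletAlpha optional concentration for Dirichlet cluster
#'   proportions; overrides equal sizes.
#' @param seed integer seed; the draw is reproducible bit-for-bit.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"counts"` (genes in rows, cells in columns, the Bioconductor
#'   orientation) and `colData` column `cluster` holding 1-based true labels.
#' @examples
#' sce <- simulateCounts(nCells = 60, nGenes = 40, kClusters = 3, seed = 1)
#' table(sce$cluster)
#' @export
simulateCounts <- function(nCells = 500, nGenes = 200, kClusters = 3,
                           meanScale = 1, logFC = 2, markersPerCluster = 20,
                           dispersion = 2, dropoutPi = 0.1,
                           lowExprFraction = 0.5, clusterProps = NULL,
                           dirichletAlpha = NULL, seed = 1) {
  stopifnot(nCells >= 1, nGenes >= 1, kClusters >= 1)
  if (markersPerCluster * kClusters > nGenes) {
    stop("markersPerCluster * kClusters must not exceed nGenes")
  }
  if (dropoutPi < 0 || dropoutPi > 1) stop("dropoutPi must lie in [0, 1]")
  if (lowExprFraction < 0 || lowExprFraction > 1) {
    stop("lowExprFraction must lie in [0, 1]")
  }
  if (meanScale <= 0 || dispersion <= 0) {
    stop("meanScale and dispersion must be positive")
  }
  set.seed(seed)

  props <- if (!is.null(clusterProps)) {
    stopifnot(length(clusterProps) == kClusters,
              abs(sum(clusterProps) - 1) < 1e-8)
    clusterProps
  } else if (!is.null(dirichletAlpha)) {
    g <- stats::rgamma(kClusters, shape = dirichletAlpha)
    g / sum(g)
  } else {
    rep(1 / kClusters, kClusters)
  }
  labels <- sort(sample.int(kClusters, nCells, replace = TRUE, prob = props))

  # baseline gene means, log-normal around meanScale
  base <- meanScale * stats::rlnorm(nGenes, meanlog = -0.125, sdlog = 0.5)
  profiles <- matrix(rep(base, each = kClusters), kClusters, nGenes)
  markerIdx <- matrix(seq_len(markersPerCluster * kClusters),
                      nrow = kClusters, byrow = TRUE)
  nLow <- round(lowExprFraction * markersPerCluster)
  for (k in seq_len(kClusters)) {
    mk <- markerIdx[k, ]
    if (nLow > 0) {
      low <- mk[seq_len(nLow)]
      profiles[, low] <- meanScale / 10          # low absolute expression
    }
    profiles[k, mk] <- profiles[k, mk] * exp(logFC)
  }

  libFactor <- stats::rlnorm(nCells, meanlog = 0, sdlog = 0.15)
  mu <- profiles[labels, , drop = FALSE] * libFactor
  counts <- matrix(
    stats::rnbinom(nCells * nGenes, size = dispersion, mu = as.numeric(mu)),
    nCells, nGenes
  )
  if (dropoutPi > 0) {
    drop <- matrix(stats::runif(nCells * nGenes) < dropoutPi, nCells, nGenes)
    counts[drop] <- 0L
  }
  dimnames(counts) <- list(sprintf("cell%04d", seq_len(nCells)),
                           sprintf("gene%04d", seq_len(nGenes)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(cluster = labels,
                                   row.names = rownames(counts)),
    metadata = list(
      profiles = profiles, libFactor = libFactor, dropoutPi = dropoutPi,
      dispersion = dispersion, seed = seed,
      config = list(nCells = nCells, nGenes = nGenes, kClusters = kClusters,
                    meanScale = meanScale, logFC = logFC,
                    markersPerCluster = markersPerCluster,
                    lowExprFraction = lowExprFraction)
    )
  )
}

#' Corrupt a count matrix by manual dropout
#'
#' Sets a uniformly random fraction `rate` of the currently nonzero entries
#' to zero, emulating aggravated technical dropout. Zero entries are left
#' untouched (zeroing them is a no-op), and the number of corrupted entries
#' is `floor(rate * nnz)` so the corruption count is deterministic. The input
#' is not mutated.
#'
#' @param counts numeric matrix of counts (any orientation), or a
#'   `SingleCellExperiment` whose `"counts"` assay is corrupted.
#' @param rate fraction of nonzero entries to zero out, in \[0, 1\].
#' @param seed integer seed for the uniform choice of entries.
#' @return object of the same class as `counts` with the corrupted matrix.
#' @export
injectDropout <- function(counts, rate, seed = 1) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    stop("rate must be a single value in [0, 1]")
  }
  if (methods::is(counts, "SingleCellExperiment")) {
    m <- SummarizedExperiment::assay(counts, "counts")
    SummarizedExperiment::assay(counts, "counts") <-
      injectDropout(as.matrix(m), rate, seed)
    return(counts)
  }
  stopifnot(is.matrix(counts))
  nz <- which(counts != 0)
  nDrop <- floor(rate * length(nz))
  if (nDrop > 0) {
    set.seed(seed)
    counts[sample(nz, nDrop)] <- 0
  }
  counts
}
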