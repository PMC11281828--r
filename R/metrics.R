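## External and internal clustering metrics, implemented from their
## pair-counting / information-theoretic definitions.

checkLabelPair <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (length(truth) < 2L) stop("at least two cells are required")
  list(truth = as.integer(factor(truth)), pred = as.integer(factor(pred)))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - [\sum_i\binom{a_i}{2}
#'   \sum_j\binom{b_j}{2}] / \binom{n}{2}}{\frac12[\sum_i\binom{a_i}{2} +
#'   \sum_j\binom{b_j}{2}] - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}] /
#'   \binom{n}{2}}}
#' over the contingency table \eqn{n_{ij}} with margins \eqn{a_i, b_j}.
#' Ranges over \[-1, 1\]; 1 means identical partitions, values near 0 arise
#' for independent labelings.
#'
#' @param truth,pred label vectors of equal length (any atomic type).
#' @return scalar ARI.
#' @export
clusterARI <- function(truth, pred) {
  lp <- checkLabelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  n <- length(lp$truth)
  sumNij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(if (sumNij == expected) 1 else 0)
  (sumNij - expected) / (maxIdx - expected)
}

#' Normalized mutual information
#'
#' \eqn{NMI = MI(L', L) / \sqrt{H(L')H(L)}} with natural-log entropies
#' (NMI is invariant to the log base). For the degenerate case of two
#' single-class labelings the value is defined as 1 (identical partitions);
#' if only one side is single-class the mutual information, and hence the
#' NMI, is 0.
#'
#' @param truth,pred label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
clusterNMI <- function(truth, pred) {
  lp <- checkLabelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  n <- length(lp$truth)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hT <- -sum(px[px > 0] * log(px[px > 0]))
  hP <- -sum(py[py > 0] * log(py[py > 0]))
  if (hT == 0 && hP == 0) return(1)
  if (hT == 0 || hP == 0) return(0)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pxy[i, j] > 0) mi <- mi + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
  }
  as.numeric(mi / sqrt(hT * hP))
}

#' Mean silhouette coefficient
#'
#' For each cell, with `a` the mean Euclidean distance to the other members
#' of its own cluster and `b` the smallest mean distance to any other
#' cluster, the silhouette is \eqn{(b - a) / \max(a, b)}; singleton clusters
#' contribute 0 for their lone member. Returns the mean over cells, in
#' \[-1, 1\].
#'
#' @param Z n x d embedding the distances are measured in.
#' @param labels cluster labels, at least two distinct values.
#' @return mean silhouette width.
#' @export
silhouetteScore <- function(Z, labels) {
  stopifnot(is.matrix(Z), nrow(Z) == length(labels))
  lab <- as.integer(factor(labels))
  K <- max(lab)
  if (K < 2L) stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(Z))
  n <- nrow(Z)
  counts <- tabulate(lab, K)
  # column sums of D within each cluster, n x K
  sums <- vapply(seq_len(K),
                 function(j) rowSums(D[, lab == j, drop = FALSE]),
                 numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab[i]
    if (counts[own] == 1L) { s[i] <- 0; next }
    a <- sums[i, own] / (counts[own] - 1L)
    b <- min(sums[i, -own] / counts[-own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
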