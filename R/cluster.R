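## Deep-embedded-clustering head: Student's-t soft assignment, target
## distribution, KL loss, Leiden centroid initialization, centroid pruning.

#' Student's-t soft cluster assignment
#'
#' \eqn{q_{ij} \propto (1 + \|z_i - \mu_j\|^2 / \alpha)^{-1}}, normalized
#' over clusters j, with `alpha` degrees of freedom (default 1, the Cauchy
#' kernel). Rows sum to one.
#'
#' @param Z n x d embedding.
#' @param centroids K x d centroid matrix.
#' @param alpha Student's-t degrees of freedom.
#' @return n x K row-stochastic soft assignment matrix Q.
#' @export
softAssign <- function(Z, centroids, alpha = 1) {
  stopifnot(is.matrix(Z), is.matrix(centroids), ncol(Z) == ncol(centroids))
  if (nrow(centroids) < 1L) stop("no live centroids")
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), "+") - 2 * tcrossprod(Z, centroids)
  d2[d2 < 0] <- 0
  qun <- (1 + d2 / alpha)^(-1)
  qun / rowSums(qun)
}

#' Sharpened target distribution
#'
#' \eqn{p_{ij} \propto q_{ij}^2 / f_j} with cluster frequency
#' \eqn{f_j = \sum_i q_{ij}}, renormalized per row. Squaring promotes
#' high-confidence assignments; dividing by frequency counteracts large
#' clusters swallowing everything.
#'
#' @param Q row-stochastic soft assignment matrix.
#' @return row-stochastic target matrix P of the same shape.
#' @export
targetDistribution <- function(Q) {
  w <- sweep(Q^2, 2L, colSums(Q), "/")
  w / rowSums(w)
}

#' Kullback-Leibler divergence between target and assignment
#'
#' \eqn{KL(P\|Q) = \sum_{ij} p_{ij} \log(p_{ij}/q_{ij})} with the
#' \eqn{0 \log 0 = 0} convention and an epsilon guard on Q.
#'
#' @param P,Q row-stochastic matrices of equal shape.
#' @param eps guard added to Q inside the log.
#' @return non-negative scalar, zero iff P equals Q.
#' @export
klLoss <- function(P, Q, eps = 1e-12) {
  if (!all(dim(P) == dim(Q))) stop("P and Q must have equal shape")
  term <- P * (log(pmax(P, eps)) - log(pmax(Q, eps)))
  term[P == 0] <- 0
  sum(term)
}

#' Initialize cluster centroids by Leiden community detection
#'
#' Builds a KNN graph on the embedding (same cosine-distance Gaussian-kernel
#' construction as the cell graph), runs the Leiden algorithm with the
#' modularity objective, and places one centroid at the mean embedding of
#' each community. The number of clusters is therefore discovered, not
#' preset; a known k, when available, is only recorded for validation.
#'
#' @param Z n x d embedding of the pretrained model.
#' @param resolution Leiden resolution parameter (default 1).
#' @param k KNN graph neighbours (default 15, capped at n - 1).
#' @param kKnown optional externally known number of clusters, stored for
#'   post-hoc comparison only — never forced.
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return list with `centroids` (K x d), `labels` (1-based community per
#'   cell), and `kKnown`.
#' @export
initCentroids <- function(Z, resolution = 1, k = 15, kKnown = NULL, seed = 1) {
  stopifnot(is.matrix(Z), nrow(Z) >= 2L)
  k <- min(k, nrow(Z) - 1L)
  g <- buildCellGraph(Z, k = k)
  W <- g$Asym
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(ig, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labels <- igraph::membership(comm)
  if (max(labels) == 1L && nrow(Z) > 1L) {
    warning("Leiden found a single community; clustering will start from K = 1")
  }
  K <- max(labels)
  centroids <- t(vapply(seq_len(K),
                        function(j) colMeans(Z[labels == j, , drop = FALSE]),
                        numeric(ncol(Z))))
  list(centroids = centroids, labels = as.integer(labels), kKnown = kKnown)
}

#' Prune under-populated cluster centroids
#'
#' Adaptively removes centroids whose hard-assigned cell count falls below
#' `minCells`, one at a time starting from the weakest, reassigning cells
#' after each removal so their mass flows to the surviving neighbours. The
#' effective number of clusters can therefore only shrink during refinement,
#' and at least one centroid always survives.
#'
#' @param Z n x d embedding.
#' @param centroids K x d centroid matrix (live centroids only).
#' @param minCells minimum hard-assignment count a centroid needs to
#'   survive. The default 1 prunes exactly the empty centroids; a fraction
#'   in (0, 1) is interpreted as a share of n.
#' @param alpha Student's-t degrees of freedom for the reassignment.
#' @return list with `centroids`, `Q`, `labels`, and `keep` (logical mask
#'   over the input centroids).
#' @export
pruneCenters <- function(Z, centroids, minCells = 1, alpha = 1) {
  if (minCells > 0 && minCells < 1) minCells <- ceiling(minCells * nrow(Z))
  keep <- rep(TRUE, nrow(centroids))
  repeat {
    Q <- softAssign(Z, centroids[keep, , drop = FALSE], alpha)
    labels <- max.col(Q, ties.method = "first")
    cnt <- tabulate(labels, nbins = sum(keep))
    if (all(cnt >= minCells) || sum(keep) == 1L) break
    keep[which(keep)[which.min(cnt)]] <- FALSE
  }
  list(centroids = centroids[keep, , drop = FALSE], Q = Q, labels = labels,
       keep = keep)
}
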