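## Graph autoencoder primitives. The trainable GAE lives in model.R on the
## autodiff tape; the functions here are the plain forward-path definitions
## used both for inference and as the reference semantics in tests.

#' One graph-convolution layer
#'
#' \eqn{Z = \tanh(\hat A \, Z_{prev} \, W)}: features are propagated over the
#' self-looped, symmetrically normalized adjacency and squashed by the
#' hyperbolic tangent, so all outputs lie in (-1, 1).
#'
#' @param Zprev n x d input features.
#' @param Ahat n x n propagation matrix from [normalizeAdjacency()].
#' @param W d x d' weight matrix.
#' @return n x d' activation matrix.
#' @export
gcnLayer <- function(Zprev, Ahat, W) {
  stopifnot(ncol(Ahat) == nrow(Zprev), ncol(Zprev) == nrow(W))
  tanh(Ahat %*% Zprev %*% W)
}

#' Dot-product decoder of the graph autoencoder
#'
#' Reconstructs the cell-cell adjacency as
#' \eqn{\tilde A = \sigma(Z Z^\top)} with the logistic sigmoid, giving a
#' symmetric matrix with entries in (0, 1).
#'
#' @param Z n x d final-layer embedding.
#' @return n x n reconstructed adjacency.
#' @export
reconstructAdjacency <- function(Z) {
  1 / (1 + exp(-tcrossprod(Z)))
}

#' Mean squared error between a graph and its reconstruction
#'
#' \eqn{L = N^{-2} \sum_{ij} (A_{ij} - \tilde A_{ij})^2}.
#'
#' @param A observed adjacency (the weighted symmetrized KNN graph, without
#'   self-loops).
#' @param Atilde reconstructed adjacency of the same shape.
#' @return non-negative scalar, zero iff the two agree exactly.
#' @export
graphLoss <- function(A, Atilde) {
  if (!all(dim(A) == dim(Atilde))) stop("A and Atilde must have equal shape")
  mean((A - Atilde)^2)
}
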