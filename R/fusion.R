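## Multi-head attention fusion of topological (GAE) and denoising (DAE)
## embeddings. Plain forward-path implementation; the trainable version in
## model.R is built from the same arithmetic on the autodiff tape and is
## tested to agree with this one.

#' Create a multi-head attention fusion block
#'
#' Allocates per-head query/key/value projections and the output projection
#' for a fusion block on embeddings of width `dim`. The per-head width is
#' `dim / nHeads` (must divide evenly), so the concatenated heads match the
#' residual width.
#'
#' @param dim embedding width the block operates on.
#' @param nHeads number of attention heads (default 8).
#' @param seed seed for Glorot-uniform initialization.
#' @return list with elements `Wq`, `Wk`, `Wv` (each a list of `nHeads`
#'   `dim x dim/nHeads` matrices) and `Wo` (`dim x dim`).
#' @export
newFusionBlock <- function(dim, nHeads = 8, seed = NULL) {
  if (dim %% nHeads != 0) stop("nHeads must divide the embedding width")
  if (!is.null(seed)) set.seed(seed)
  dh <- dim %/% nHeads
  mk <- function() lapply(seq_len(nHeads), function(i) glorot(dim, dh))
  list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = glorot(dim, dim),
       nHeads = nHeads, dim = dim)
}

#' Fuse topological and denoising embeddings by multi-head attention
#'
#' Queries come from the graph-autoencoder embedding `Z`, keys and values
#' from the denoising-autoencoder embedding `E`. Per head m the attention is
#' \eqn{a_m = \mathrm{softmax}(Q_m K_m^\top)} (row-wise; unscaled dot product
#' by default, with an optional \eqn{1/\sqrt{d_k}} scaling), the head output
#' is \eqn{a_m V_m}, and the block output is
#' \eqn{R = \mathrm{Concat}(heads)\,W_o + E} — a residual on the denoising
#' embedding plus a row-stochastic mixture of value projections.
#'
#' @param Z n x dim graph embedding (queries).
#' @param E n x dim denoising embedding (keys/values and residual).
#' @param block a block from [newFusionBlock()].
#' @param scaled divide scores by sqrt of the per-head width before the
#'   softmax (off by default, matching the unscaled dot-product definition).
#' @return list with `R` (n x dim fused output) and `attention` (list of the
#'   per-head row-stochastic attention matrices).
#' @export
attentionFuse <- function(Z, E, block, scaled = FALSE) {
  stopifnot(nrow(Z) == nrow(E), ncol(Z) == block$dim, ncol(E) == block$dim)
  dh <- block$dim %/% block$nHeads
  heads <- vector("list", block$nHeads)
  attn <- vector("list", block$nHeads)
  for (m in seq_len(block$nHeads)) {
    Q <- Z %*% block$Wq[[m]]
    K <- E %*% block$Wk[[m]]
    V <- E %*% block$Wv[[m]]
    S <- tcrossprod(Q, K)
    if (scaled) S <- S / sqrt(dh)
    S <- S - apply(S, 1L, max)
    a <- exp(S)
    a <- a / rowSums(a)
    attn[[m]] <- a
    heads[[m]] <- a %*% V
  }
  R <- do.call(cbind, heads) %*% block$Wo + E
  list(R = R, attention = attn)
}
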