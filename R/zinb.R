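#' Re-weight low-expression gene columns for the ZINB loss
#'
#' Builds the loss-side matrix \eqn{X'} that biases the ZINB reconstruction
#' likelihood towards lowly expressed highly variable genes. With `m` genes
#' ordered by total expression (descending, the contract established by
#' [selectOrderHVGs()]), the first \eqn{k = \lfloor tailorRate \cdot m \rfloor}
#' columns are left untouched and the remaining low-expression columns are
#' multiplied by `lossRate`. The input matrix itself is never modified; only
#' the likelihood sees \eqn{X'}.
#'
#' @param X numeric matrix of counts, cells in rows, genes in columns ordered
#'   by decreasing total expression.
#' @param tailorRate proportion of high-expression columns left unscaled, in
#'   (0, 1]. Default 0.9.
#' @param lossRate multiplicative magnification applied to the remaining
#'   low-expression columns, >= 0. Default 2.
#' @param checkOrder verify the column-ordering contract (non-increasing
#'   column totals) and error if violated.
#' @return matrix `X'` of the same shape as `X`.
#' @examples
#' X <- matrix(1, 1, 10)
#' tailorTransform(X, tailorRate = 0.9, lossRate = 2, checkOrder = FALSE)
#' @export
tailorTransform <- function(X, tailorRate = 0.9, lossRate = 2,
                            checkOrder = TRUE) {
  stopifnot(is.matrix(X))
  if (!(tailorRate > 0 && tailorRate <= 1)) {
    stop("tailorRate must lie in (0, 1]")
  }
  if (lossRate < 0) stop("lossRate must be non-negative")
  m <- ncol(X)
  if (checkOrder && m > 1L) {
    tot <- colSums(X)
    if (any(diff(tot) > 1e-8)) {
      stop("columns of X must be ordered by non-increasing total expression; ",
           "run selectOrderHVGs() first")
    }
  }
  k <- floor(tailorRate * m)
  Xp <- X
  if (lossRate == 1) return(Xp)
  if (k < m) {
    Xp[, (k + 1L):m] <- lossRate * Xp[, (k + 1L):m]
  }
  Xp
}

#' Negative binomial log density in its gamma-function form
#'
#' Log probability mass of the negative binomial distribution with mean `mu`
#' and dispersion `theta`, written through log-gamma functions so that it is
#' well defined for non-integer `x` (the loss-side counts can be non-integer
#' after [tailorTransform()] with a non-integer loss rate).
#'
#' @param x non-negative values (real-valued allowed); recycled with `mu`,
#'   `theta`.
#' @param mu positive mean.
#' @param theta positive dispersion (inverse overdispersion; variance is
#'   `mu + mu^2 / theta`).
#' @return log density, same shape as the broadcast arguments.
#' @export
nbLogPmf <- function(x, mu, theta) {
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  lgamma(x + theta) - lgamma(x + 1) - lgamma(theta) +
    theta * log(theta / (theta + mu)) + x * log(mu / (theta + mu))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' The ZINB model is a mixture of a point mass at zero (probability `pi`) and
#' NB(`mu`, `theta`). For a zero observation the likelihood is
#' \eqn{\pi + (1-\pi)(\theta/(\theta+\mu))^\theta}; for a positive one it is
#' \eqn{(1-\pi)} times the NB density. The loss is the summed (or averaged)
#' negative log-likelihood over all entries.
#'
#' When the loss is evaluated on the re-weighted matrix \eqn{X'} from
#' [tailorTransform()], the zero/nonzero decision is taken on the original
#' counts via `zeroMask` (scaling cannot turn a nonzero into a zero, so the
#' two conventions agree; the mask keeps intent explicit).
#'
#' @param X count matrix (possibly the re-weighted `X'`).
#' @param pi,mu,theta ZINB parameter matrices, same shape as `X`; `pi` in
#'   (0,1), `mu`, `theta` positive.
#' @param eps numeric guard added inside logarithms. Default 1e-10.
#' @param reduction `"mean"` or `"sum"` over entries.
#' @param zeroMask optional logical matrix marking entries treated as zeros;
#'   defaults to `X == 0`.
#' @return scalar negative log-likelihood.
#' @export
zinbNLL <- function(X, pi, mu, theta, eps = 1e-10,
                    reduction = c("mean", "sum"), zeroMask = NULL) {
  reduction <- match.arg(reduction)
  if (!all(dim(X) == dim(pi)) || !all(dim(X) == dim(mu)) ||
      !all(dim(X) == dim(theta))) {
    stop("X, pi, mu, theta must have identical shapes")
  }
  if (any(pi <= 0) || any(pi >= 1)) stop("pi must lie strictly in (0, 1)")
  if (is.null(zeroMask)) zeroMask <- X == 0
  nb0 <- exp(theta * log(theta / (theta + mu)))
  llZero <- log(pi + (1 - pi) * nb0 + eps)
  llPos <- log(1 - pi + eps) + nbLogPmf(pmax(X, 0), mu, theta)
  nll <- -(ifelse(zeroMask, llZero, llPos))
  if (reduction == "mean") mean(nll) else sum(nll)
}
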