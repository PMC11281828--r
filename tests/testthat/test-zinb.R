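# The re-weighted (low-expression-biased) ZINB loss and its components.

test_that("tailorTransform scales exactly the trailing low-expression columns", {
  # identity when lossRate = 1, for any tailor rate
  X <- matrix(rpois(40, 3), 4, 10)
  X <- X[, order(colSums(X), decreasing = TRUE)]
  expect_identical(tailorTransform(X, 0.37, 1), X)

  # published defaults on a 1 x 10 all-ones row: only the last column scales
  ones <- matrix(1, 1, 10)
  expect_equal(as.numeric(tailorTransform(ones, 0.9, 2, checkOrder = FALSE)),
               c(rep(1, 9), 2))

  # floor rule: tailorRate 0.5 on 7 genes -> k = 3, columns 4:7 scaled
  X7 <- matrix(rep(7:1, each = 2), 2, 7)
  out <- tailorTransform(X7, 0.5, 3)
  expect_equal(out[, 1:3], X7[, 1:3])
  expect_equal(out[, 4:7], 3 * X7[, 4:7])

  # the input itself is never modified
  before <- X7[1, 7]
  invisible(tailorTransform(X7, 0.5, 3))
  expect_equal(X7[1, 7], before)

  # ordering contract enforced
  bad <- matrix(c(1, 1, 5, 5), 2, 2)
  expect_error(tailorTransform(bad), "ordered")
})

test_that("nbLogPmf matches the factorial-form oracle and normalizes", {
  # geometric special case: theta = mu = 1 has pmf (1/2)^(x+1)
  expect_equal(nbLogPmf(2, 1, 1), log(0.125), tolerance = 1e-12)
  # closed form at zero
  expect_equal(nbLogPmf(0, 3, 2), 2 * log(2 / 5), tolerance = 1e-12)
  # normalization: sums to 1 over the support
  expect_equal(sum(exp(nbLogPmf(0:50, 1, 1))), 1, tolerance = 1e-10)

  for (mu in c(0.1, 1, 10)) for (th in c(0.1, 1, 10)) for (x in 0:10) {
    expect_equal(nbLogPmf(x, mu, th), log(oracleNbPmf(x, mu, th)),
                 tolerance = 1e-8)
  }
  expect_error(nbLogPmf(1, -1, 1), "positive")
})

test_that("zinbNLL handles the zero mixture and degenerates to plain NB", {
  # hand evaluation of the mixture at zero
  x0 <- matrix(0, 1, 1)
  expect_equal(zinbNLL(x0, matrix(0.5, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                       eps = 0),
               -log(0.75), tolerance = 1e-12)

  # pi -> 1 at a zero observation explains it fully: NLL -> 0
  expect_lt(zinbNLL(x0, matrix(1 - 1e-12, 1, 1), matrix(5, 1, 1),
                    matrix(1, 1, 1), eps = 0), 1e-10)

  # pi -> 0 recovers the plain NB NLL
  set.seed(31)
  X <- matrix(rpois(20, 2), 4, 5)
  mu <- matrix(runif(20, 0.5, 3), 4, 5)
  th <- matrix(runif(20, 0.5, 3), 4, 5)
  tiny <- matrix(1e-300, 4, 5)
  expect_equal(zinbNLL(X, tiny, mu, th, eps = 0, reduction = "sum"),
               -sum(ifelse(X == 0, th * log(th / (th + mu)),
                           nbLogPmf(X, mu, th))),
               tolerance = 1e-8)
  expect_error(zinbNLL(X, tiny[, 1:3], mu, th), "shapes")
})

test_that("re-weighted loss reduces to the standard loss at lossRate 1 and is monotone in lossRate", {
  set.seed(32)
  X <- matrix(rpois(60, 2), 6, 10)
  X <- X[, order(colSums(X), decreasing = TRUE)]
  p <- matrix(runif(60, 0.1, 0.9), 6, 10)
  mu <- matrix(runif(60, 0.5, 4), 6, 10)
  th <- matrix(runif(60, 0.5, 4), 6, 10)
  mask <- X == 0

  lossAt <- function(lr) {
    Xp <- tailorTransform(X, 0.9, lr)
    zinbNLL(Xp, p, mu, th, zeroMask = mask)
  }
  # bit-for-bit identity at lossRate = 1
  expect_identical(lossAt(1), zinbNLL(X, p, mu, th))

  # per-entry monotonicity: scaling any nonzero low-expression entry up
  # strictly increases its NLL contribution (x log(mu/(theta+mu)) decreases)
  k <- floor(0.9 * 10)
  lowCols <- (k + 1):10
  entries <- which(X[, lowCols, drop = FALSE] > 0)
  expect_gt(length(entries), 0)
  l1 <- -nbLogPmf(X[, lowCols], mu[, lowCols], th[, lowCols])
  l2 <- -nbLogPmf(2 * X[, lowCols], mu[, lowCols], th[, lowCols])
  l3 <- -nbLogPmf(3 * X[, lowCols], mu[, lowCols], th[, lowCols])
  # compare the x-affine part: differences grow with the scaling factor
  affine <- function(s) -s * X[, lowCols] * log(mu[, lowCols] /
                                                (th[, lowCols] + mu[, lowCols]))
  expect_true(all((affine(3) - affine(2))[entries] > 0))
})

test_that("direct optimization of zinbNLL recovers the generating parameters", {
  set.seed(33)
  n <- 10000
  piT <- 0.25; muT <- 4; thT <- 1.5
  x <- rnbinom(n, size = thT, mu = muT)
  x[runif(n) < piT] <- 0
  X <- matrix(x, 1)
  nll <- function(par) {
    p <- plogis(par[1]); m <- exp(par[2]); t <- exp(par[3])
    zinbNLL(X, matrix(p, 1, n), matrix(m, 1, n), matrix(t, 1, n))
  }
  fit <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_lt(abs(plogis(fit$par[1]) - piT), 0.05)
  expect_lt(abs(exp(fit$par[2]) - muT), 0.3)
  expect_lt(abs(exp(fit$par[3]) - thT), 0.3)
})
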