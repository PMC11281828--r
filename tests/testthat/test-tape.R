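# The autodiff tape is the numerical core every network rests on; each
# primitive and each fused composite is checked against central finite
# differences on small random instances.

tp <- scFuseClust:::newTape
leaf <- scFuseClust:::tpLeaf
bwd <- scFuseClust:::tpBackward

test_that("primitive ops match finite-difference gradients", {
  set.seed(7)
  W <- matrix(rnorm(12), 4, 3)
  X <- matrix(rnorm(8), 2, 4)
  b <- matrix(rnorm(3), 1, 3)

  lossFn <- function(w) {
    tape <- tp()
    wN <- leaf(tape, w)
    xN <- leaf(tape, X)
    bN <- leaf(tape, b)
    h <- scFuseClust:::tpTanh(tape, scFuseClust:::tpAdd(tape,
           scFuseClust:::tpMatmul(tape, xN, wN), bN))
    s <- scFuseClust:::tpSigmoid(tape, h)
    scFuseClust:::tpMean(tape, scFuseClust:::tpMul(tape, s, s))
  }
  tape <- tp()
  wN <- leaf(tape, W); xN <- leaf(tape, X); bN <- leaf(tape, b)
  h <- scFuseClust:::tpTanh(tape, scFuseClust:::tpAdd(tape,
         scFuseClust:::tpMatmul(tape, xN, wN), bN))
  s <- scFuseClust:::tpSigmoid(tape, h)
  loss <- scFuseClust:::tpMean(tape, scFuseClust:::tpMul(tape, s, s))
  bwd(tape, loss)

  gNum <- numericalGrad(function(w) lossFn(w)$val[1], W)
  expect_lt(max(abs(wN$grad - gNum)), 1e-6)

  gNumB <- numericalGrad(function(bb) {
    tape <- tp(); wN <- leaf(tape, W); xN <- leaf(tape, X); bN <- leaf(tape, bb)
    h <- scFuseClust:::tpTanh(tape, scFuseClust:::tpAdd(tape,
           scFuseClust:::tpMatmul(tape, xN, wN), bN))
    s <- scFuseClust:::tpSigmoid(tape, h)
    scFuseClust:::tpMean(tape, scFuseClust:::tpMul(tape, s, s))$val[1]
  }, b)
  expect_lt(max(abs(bN$grad - gNumB)), 1e-6)
})

test_that("lgamma, exp, log, div primitives differentiate correctly", {
  set.seed(8)
  X <- matrix(runif(6, 0.5, 3), 2, 3)
  f <- function(x) {
    tape <- tp()
    xN <- leaf(tape, x)
    lg <- scFuseClust:::tpLgamma(tape, xN)
    ex <- scFuseClust:::tpExp(tape, scFuseClust:::tpScale(tape, xN, 0.3))
    lo <- scFuseClust:::tpLog(tape, scFuseClust:::tpShift(tape, xN, 1))
    dv <- scFuseClust:::tpDiv(tape, lg, scFuseClust:::tpShift(tape, ex, 2))
    list(tape = tape, xN = xN,
         loss = scFuseClust:::tpSum(tape, scFuseClust:::tpAdd(tape, dv, lo)))
  }
  r <- f(X)
  bwd(r$tape, r$loss)
  gNum <- numericalGrad(function(x) f(x)$loss$val[1], X)
  expect_lt(max(abs(r$xN$grad - gNum)), 1e-5)
})

test_that("fused attention head matches its formula and finite differences", {
  set.seed(9)
  n <- 5; d <- 4; dh <- 2
  Q0 <- matrix(rnorm(n * dh), n, dh)
  K0 <- matrix(rnorm(n * dh), n, dh)
  V0 <- matrix(rnorm(n * dh), n, dh)

  tape <- tp()
  Qn <- leaf(tape, Q0); Kn <- leaf(tape, K0); Vn <- leaf(tape, V0)
  out <- scFuseClust:::tpAttentionHead(tape, Qn, Kn, Vn)
  # forward agrees with a hand-rolled softmax
  S <- Q0 %*% t(K0)
  a <- exp(S - apply(S, 1, max)); a <- a / rowSums(a)
  expect_equal(out$val, a %*% V0, tolerance = 1e-12)

  loss <- scFuseClust:::tpSum(tape, scFuseClust:::tpMul(tape, out, out))
  bwd(tape, loss)
  evalLoss <- function(Q, K, V) {
    S <- Q %*% t(K); a <- exp(S - apply(S, 1, max)); a <- a / rowSums(a)
    sum((a %*% V)^2)
  }
  gQ <- numericalGrad(function(w) evalLoss(w, K0, V0), Q0)
  gK <- numericalGrad(function(w) evalLoss(Q0, w, V0), K0)
  gV <- numericalGrad(function(w) evalLoss(Q0, K0, w), V0)
  expect_lt(max(abs(Qn$grad - gQ)), 1e-6)
  expect_lt(max(abs(Kn$grad - gK)), 1e-6)
  expect_lt(max(abs(Vn$grad - gV)), 1e-6)
})

test_that("fused graph-reconstruction and ZINB losses match finite differences", {
  set.seed(10)
  n <- 6
  Z0 <- matrix(rnorm(n * 3, sd = 0.5), n, 3)
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0

  tape <- tp()
  Zn <- leaf(tape, Z0)
  loss <- scFuseClust:::tpGraphReconMSE(tape, Zn, A)
  expect_equal(loss$val[1], graphLoss(A, reconstructAdjacency(Z0)),
               tolerance = 1e-12)
  bwd(tape, loss)
  gZ <- numericalGrad(function(z) graphLoss(A, reconstructAdjacency(z)), Z0)
  expect_lt(max(abs(Zn$grad - gZ)), 1e-6)

  X <- matrix(rpois(12, 2), 3, 4)
  mask <- (X == 0) * 1
  p0 <- matrix(runif(12, 0.2, 0.8), 3, 4)
  m0 <- matrix(runif(12, 0.5, 3), 3, 4)
  t0 <- matrix(runif(12, 0.5, 3), 3, 4)
  tape <- tp()
  pN <- leaf(tape, p0); mN <- leaf(tape, m0); tN <- leaf(tape, t0)
  loss <- scFuseClust:::tpZinbLoss(tape, X, mask, pN, mN, tN)
  expect_equal(loss$val[1], zinbNLL(X, p0, m0, t0), tolerance = 1e-10)
  bwd(tape, loss)
  expect_lt(max(abs(pN$grad - numericalGrad(function(w) zinbNLL(X, w, m0, t0), p0))), 1e-5)
  expect_lt(max(abs(mN$grad - numericalGrad(function(w) zinbNLL(X, p0, w, t0), m0))), 1e-5)
  expect_lt(max(abs(tN$grad - numericalGrad(function(w) zinbNLL(X, p0, m0, w), t0))), 1e-5)
})

test_that("fused Student-t assignment matches softAssign and finite differences", {
  set.seed(11)
  Z0 <- matrix(rnorm(10), 5, 2)
  C0 <- matrix(rnorm(6), 3, 2)
  tape <- tp()
  Zn <- leaf(tape, Z0); Cn <- leaf(tape, C0)
  Qn <- scFuseClust:::tpStudentQ(tape, Zn, Cn, alpha = 1)
  expect_equal(Qn$val, softAssign(Z0, C0), tolerance = 1e-12)
  loss <- scFuseClust:::tpSum(tape, scFuseClust:::tpMul(tape, Qn, Qn))
  bwd(tape, loss)
  f <- function(Z, C) sum(softAssign(Z, C)^2)
  expect_lt(max(abs(Zn$grad - numericalGrad(function(w) f(w, C0), Z0))), 1e-6)
  expect_lt(max(abs(Cn$grad - numericalGrad(function(w) f(Z0, w), C0))), 1e-6)
})

test_that("Adam with gradient clipping reduces a quadratic objective", {
  set.seed(12)
  target <- matrix(rnorm(6), 2, 3)
  params <- list(W = matrix(0, 2, 3))
  st <- scFuseClust:::adamInit(params)
  lossAt <- function(W) sum((W - target)^2)
  l0 <- lossAt(params$W)
  for (i in 1:200) {
    g <- list(W = 2 * (params$W - target))
    stp <- scFuseClust:::adamStep(params, g, st, lr = 0.05, clipNorm = 3)
    params <- stp$params; st <- stp$state
  }
  expect_lt(lossAt(params$W), l0 / 100)
})
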