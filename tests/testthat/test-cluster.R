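# DEC head: soft assignment, target distribution, KL loss, Leiden
# initialization, pruning, and the training loop's contracts.

test_that("soft assignment follows the Student's-t kernel", {
  # single centroid: probability 1
  Z <- matrix(c(1, 2), 1, 2)
  expect_equal(softAssign(Z, Z), matrix(1, 1, 1))

  # equidistant point between two centroids
  C <- rbind(c(0, 0), c(2, 0))
  expect_equal(as.numeric(softAssign(matrix(c(1, 0), 1, 2), C)), c(0.5, 0.5))

  # distances 1 and 2 with alpha = 1: q = (5/7, 2/7)
  C2 <- rbind(c(1, 0), c(2, 0))
  zq <- matrix(c(0, 0), 1, 2)
  expect_equal(as.numeric(softAssign(zq, C2)), c(5 / 7, 2 / 7),
               tolerance = 1e-12)

  # rows always sum to one
  set.seed(61)
  Q <- softAssign(matrix(rnorm(40), 10, 4), matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(Q), rep(1, 10))
  expect_error(softAssign(matrix(0, 2, 2), matrix(0, 0, 2)), "centroids")
})

test_that("target distribution sharpens as q^2 over cluster frequency", {
  # n = 1: P reduces to Q algebraically
  Q1 <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(targetDistribution(Q1), Q1, tolerance = 1e-12)

  # hand evaluation for two cells
  Q <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  P <- targetDistribution(Q)
  f <- colSums(Q)
  w <- sweep(Q^2, 2, f, "/")
  expect_equal(P, w / rowSums(w), tolerance = 1e-12)
  # f = (1.5, 0.5); row 1 weights (0.81/1.5, 0.01/0.5) = (0.54, 0.02)
  expect_equal(P[1, ], c(0.54, 0.02) / 0.56, tolerance = 1e-12)

  set.seed(62)
  Qr <- matrix(runif(50), 10, 5); Qr <- Qr / rowSums(Qr)
  expect_lt(max(abs(rowSums(targetDistribution(Qr)) - 1)), 1e-9)
})

test_that("KL divergence is a proper divergence with the 0 log 0 convention", {
  Q <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(klLoss(Q, Q), 0)
  expect_equal(klLoss(matrix(c(1, 0), 1, 2), Q), log(2), tolerance = 1e-9)
  set.seed(63)
  for (i in 1:20) {
    P <- matrix(runif(8), 2, 4); P <- P / rowSums(P)
    Qr <- matrix(runif(8), 2, 4); Qr <- Qr / rowSums(Qr)
    expect_gte(klLoss(P, Qr), 0)
  }
  expect_error(klLoss(Q, matrix(0.25, 1, 4)), "shape")
})

test_that("Leiden initialization finds well-separated blobs and is seeded", {
  set.seed(64)
  # blobs placed off the origin (cosine distance degenerates around zero)
  blob1 <- cbind(rnorm(20, 5, 0.2), rnorm(20, 0, 0.2))
  blob2 <- cbind(rnorm(20, 0, 0.2), rnorm(20, 5, 0.2))
  Z <- rbind(blob1, blob2)
  init <- initCentroids(Z, k = 11, seed = 7)
  expect_equal(nrow(init$centroids), 2)
  means <- rbind(colMeans(blob1), colMeans(blob2))
  dists <- apply(init$centroids, 1,
                 function(c) min(sqrt(rowSums((means - rep(c, each = 2))^2))))
  expect_lt(max(dists), 0.1)

  init2 <- initCentroids(Z, k = 11, seed = 7)
  expect_identical(init$labels, init2$labels)

  # identical points collapse to one community (warning, K = 1)
  same <- matrix(1, 10, 2)
  expect_warning(one <- initCentroids(same, k = 3, seed = 1), "single community")
  expect_equal(nrow(one$centroids), 1)
  expect_equal(as.numeric(one$centroids), c(1, 1))
})

test_that("pruning removes only under-populated centroids and renormalizes Q", {
  set.seed(65)
  Z <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 4, 0.1), 20, 2))
  # two good centroids and one far-away dead centroid
  C <- rbind(c(0, 0), c(4, 4) * 0 + 4, c(50, 50))
  pr <- pruneCenters(Z, C, minCells = 1)
  expect_equal(nrow(pr$centroids), 2)
  expect_equal(pr$keep, c(TRUE, TRUE, FALSE))
  expect_equal(rowSums(pr$Q), rep(1, 40))

  # all centroids sufficiently populated: no-op
  pr2 <- pruneCenters(Z, C[1:2, ], minCells = 1)
  expect_true(all(pr2$keep))

  # pruning never empties the state: the largest centroid survives
  pr3 <- pruneCenters(Z, C, minCells = 1000)
  expect_equal(nrow(pr3$centroids), 1)
})

test_that("full training recovers planted clusters and its K never grows", {
  sim <- simulateCounts(nCells = 200, nGenes = 80, kClusters = 3,
                        markersPerCluster = 10, seed = 66)
  cfg <- scfConfig(pretrainEpochs = 15, finetuneEpochs = 30,
                   updateInterval = 5, seed = 66)
  res <- scfPipeline(sim, cfg)
  expect_gte(res$metrics$ari, 0.9)
  h <- trainHistory(res$fit)
  kTrace <- h$kEff[h$phase == "finetune" & !is.na(h$kEff)]
  expect_true(all(diff(kTrace) <= 0))

  # determinism: identical seeds give identical labels
  res2 <- scfPipeline(sim, cfg)
  expect_identical(clusterLabels(res$fit), clusterLabels(res2$fit))
})

test_that("over-initialized centroids are pruned down on separable data", {
  sim <- simulateCounts(nCells = 150, nGenes = 60, kClusters = 3,
                        markersPerCluster = 8, seed = 67)
  # high Leiden resolution to over-partition; fractional minCells lets the
  # refinement drop under-populated centroids
  cfg <- scfConfig(pretrainEpochs = 15, finetuneEpochs = 40,
                   updateInterval = 5, leidenResolution = 4,
                   minCells = 0.1, seed = 67)
  res <- scfPipeline(sim, cfg)
  h <- trainHistory(res$fit)
  kTrace <- h$kEff[h$phase == "finetune" & !is.na(h$kEff)]
  expect_true(all(diff(kTrace) <= 0))
  expect_gt(res$fit@kInit, nrow(res$fit@centroids))
  # the surviving partition refines the truth: every found cluster is pure
  purity <- vapply(split(sim$cluster, clusterLabels(res$fit)),
                   function(tr) max(table(tr)) / length(tr), 0)
  expect_gt(mean(purity), 0.9)
})

test_that("early stopping fires when labels are frozen", {
  sim <- simulateCounts(nCells = 100, nGenes = 40, kClusters = 2,
                        markersPerCluster = 6, seed = 68)
  # zero learning rate after initialization: labels cannot change, so the
  # first checkpoint must trigger the early stop
  cfg <- scfConfig(pretrainEpochs = 5, finetuneEpochs = 50,
                   updateInterval = 5, seed = 68)
  cfg$lr <- 1e-12
  res <- scfPipeline(sim, cfg)
  h <- trainHistory(res$fit)
  ft <- h[h$phase == "finetune", ]
  expect_lt(max(ft$epoch), 50)
  expect_lt(ft$labelChange[nrow(ft)], 1e-3)
})
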