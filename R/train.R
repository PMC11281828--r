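## Two-phase training: (1) pretraining of the fused autoencoders under
## L_train = L_zinb + r1 * L_graph; (2) DEC fine-tuning of
## L = L_KL + r2 * L_train with Leiden-initialized centroids, target-
## distribution updates, adaptive centroid pruning, and early stopping on
## the label-change fraction.

#' Assemble and validate the run configuration
#'
#' The defaults are the method's standard operating point: tailor rate 0.9,
#' loss rate 2, balance weights r1 = r2 = 0.1, Adam with learning rate 0.001
#' and gradient L2-norm clip 3, Gaussian input noise with variance 0.01,
#' eight attention heads, Student's-t degrees of freedom 1, early stop when
#' fewer than 1/1000 of cells change label between target updates. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return validated named list.
#' @export
scfConfig <- function(...) {
  defaults <- list(
    nHVG = NULL, kNeighbors = 15, hvgFlavor = "dispersion",
    sigmaMode = "local", binarize = FALSE, targetSum = NULL,
    tailorRate = 0.9, lossRate = 2, zinbEps = 1e-10,
    noiseSD = 0.1, shareReduction = TRUE,
    nHeads = 8, scaledAttention = FALSE,
    r1 = 0.1, r2 = 0.1, lr = 1e-3, clipNorm = 3,
    pretrainEpochs = 30, finetuneEpochs = 60, updateInterval = 10,
    earlyStopTol = 1e-3, leidenResolution = 1, minCells = 1, alpha = 1,
    noAttention = FALSE, noGAE = FALSE, noDAE = FALSE, noTailor = FALSE,
    seed = 1
  )
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1L]])) ov <- ov[[1L]]
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov, keep.null = TRUE)
  stopifnot(cfg$tailorRate > 0, cfg$tailorRate <= 1, cfg$lossRate >= 0,
            cfg$r1 >= 0, cfg$r2 >= 0, cfg$lr > 0, cfg$noiseSD >= 0,
            cfg$updateInterval >= 1, cfg$earlyStopTol > 0)
  if (cfg$noDAE && cfg$noGAE) stop("cannot ablate both the DAE and the GAE")
  if (cfg$noTailor) cfg$lossRate <- 1
  cfg
}

#' Fitted clustering model
#'
#' @slot labels final hard cluster labels (1-based, relabelled to consecutive
#'   integers).
#' @slot embedding the fused clustering representation R2, cells in rows.
#' @slot centroids live centroid matrix in embedding space.
#' @slot Q final soft assignment matrix.
#' @slot history per-epoch log: phase, epoch, losses, effective number of
#'   clusters, and label-change fraction at target updates.
#' @slot kInit number of centroids the Leiden initialization proposed.
#' @slot config the resolved configuration list.
#' @export
setClass("ScfFit", representation(
  labels = "integer", embedding = "matrix", centroids = "matrix",
  Q = "matrix", history = "data.frame", kInit = "integer", config = "list"
))

setValidity("ScfFit", function(object) {
  if (length(object@labels) != nrow(object@embedding)) {
    return("labels and embedding disagree on the number of cells")
  }
  TRUE
})

#' @describeIn ScfFit compact description
#' @param object a `ScfFit`.
#' @export
setMethod("show", "ScfFit", function(object) {
  cat("ScfFit:", length(object@labels), "cells,",
      nrow(object@centroids), "clusters (initialized at",
      object@kInit, "by Leiden)\n")
})

#' @rdname ScfFit-class
#' @param x a `ScfFit`.
#' @export
clusterLabels <- function(x) {
  stopifnot(methods::is(x, "ScfFit"))
  x@labels
}

#' @rdname ScfFit-class
#' @export
cellEmbedding <- function(x) {
  stopifnot(methods::is(x, "ScfFit"))
  x@embedding
}

#' @rdname ScfFit-class
#' @export
trainHistory <- function(x) {
  stopifnot(methods::is(x, "ScfFit"))
  x@history
}

collectGrads <- function(leaves, params) {
  g <- lapply(names(params), function(nm) {
    gr <- leaves[[nm]]$grad
    if (is.null(gr)) params[[nm]] * 0 else gr
  })
  names(g) <- names(params)
  g
}

#' Train the fused clustering model on preprocessed data
#'
#' Runs the pretraining and fine-tuning phases and returns a [ScfFit-class].
#' With `trueLabels` supplied, the per-epoch ARI is logged (evaluation only;
#' the labels never influence training).
#'
#' @param prep a [ScfPreprocessed-class] from [preprocessCounts()].
#' @param config a list from [scfConfig()].
#' @param trueLabels optional ground-truth labels for logging.
#' @param verbose print a line per target update.
#' @return a [ScfFit-class].
#' @export
scfTrain <- function(prep, config = scfConfig(), trueLabels = NULL,
                     verbose = FALSE) {
  stopifnot(methods::is(prep, "ScfPreprocessed"))
  cfg <- config
  set.seed(cfg$seed)
  n <- nrow(prep@X)
  m <- ncol(prep@X)

  data <- list(
    Xbar = prep@Xbar,
    Ahat = Matrix::Matrix(prep@graph$Ahat, sparse = TRUE),
    Asym = prep@graph$Asym,
    sizeFactors = prep@sizeFactors,
    Xprime = tailorTransform(prep@X, cfg$tailorRate, cfg$lossRate),
    zeroMask = (prep@X == 0) * 1
  )

  params <- initModelParams(m, cfg)
  opt <- adamInit(params)
  hist <- list()

  logRow <- function(phase, epoch, fw, kEff, change = NA_real_, ari = NA_real_) {
    hist[[length(hist) + 1L]] <<- data.frame(
      phase = phase, epoch = epoch,
      lZinb = if (!is.null(fw$lZinb)) fw$lZinb$val[1] else NA_real_,
      lGraph = if (!is.null(fw$lGraph)) fw$lGraph$val[1] else NA_real_,
      lKL = if (!is.null(fw$lKL)) fw$lKL$val[1] else NA_real_,
      kEff = kEff, labelChange = change, ari = ari
    )
  }

  ## ---- phase 1: pretrain ----
  for (ep in seq_len(cfg$pretrainEpochs)) {
    fw <- modelForward(params, data, cfg, noiseOn = TRUE)
    tpBackward(fw$tape, fw$lTrain)
    step <- adamStep(params, collectGrads(fw$leaves, params), opt,
                     lr = cfg$lr, clipNorm = cfg$clipNorm)
    params <- step$params
    opt <- step$state
    if (!is.finite(fw$lTrain$val[1])) stop("pretraining loss diverged (NaN)")
    logRow("pretrain", ep, fw, NA_integer_)
  }

  ## ---- centroid initialization on the noise-free embedding ----
  fw <- modelForward(params, data, cfg, noiseOn = FALSE)
  Zemb <- fw$R2$val
  init <- initCentroids(Zemb, resolution = cfg$leidenResolution,
                        k = min(cfg$kNeighbors, n - 1L), seed = cfg$seed)
  kInit <- nrow(init$centroids)
  pr <- pruneCenters(Zemb, init$centroids, minCells = cfg$minCells,
                     alpha = cfg$alpha)
  centroids <- pr$centroids
  opt$m$centroids <- centroids * 0
  opt$v$centroids <- centroids * 0

  # physical centroid identities survive pruning so the label-change
  # fraction compares like with like across checkpoints
  centroidIds <- seq_len(nrow(centroids))
  labelsPrev <- centroidIds[pr$labels]
  Pmat <- targetDistribution(pr$Q)

  ## ---- phase 2: fine-tune ----
  for (ep in seq_len(cfg$finetuneEpochs)) {
    if (ep > 1L && (ep - 1L) %% cfg$updateInterval == 0L) {
      fwEval <- modelForward(params, data, cfg, noiseOn = FALSE,
                             centroids = centroids)
      pr <- pruneCenters(fwEval$R2$val, centroids, minCells = cfg$minCells,
                         alpha = cfg$alpha)
      if (!all(pr$keep)) {
        centroids <- pr$centroids
        opt$m$centroids <- opt$m$centroids[pr$keep, , drop = FALSE]
        opt$v$centroids <- opt$v$centroids[pr$keep, , drop = FALSE]
        centroidIds <- centroidIds[pr$keep]
      }
      Pmat <- targetDistribution(pr$Q)
      labelsNow <- centroidIds[pr$labels]
      change <- mean(labelsNow != labelsPrev)
      if (verbose) {
        message(sprintf("fine-tune epoch %d: K = %d, label change %.4f",
                        ep, nrow(centroids), change))
      }
      labelsPrev <- labelsNow
      if (change < cfg$earlyStopTol) {
        logRow("finetune", ep, fwEval, nrow(centroids), change,
               if (!is.null(trueLabels)) clusterARI(trueLabels, pr$labels) else NA_real_)
        break
      }
    }
    allP <- c(params, list(centroids = centroids))
    fw <- modelForward(params, data, cfg, noiseOn = TRUE,
                       centroids = centroids, Pconst = Pmat)
    tpBackward(fw$tape, fw$loss)
    grads <- collectGrads(fw$leaves, params)
    gC <- fw$centroidLeaf$grad
    grads$centroids <- if (is.null(gC)) centroids * 0 else gC
    step <- adamStep(allP, grads, opt, lr = cfg$lr, clipNorm = cfg$clipNorm)
    params <- step$params[names(params)]
    centroids <- step$params$centroids
    opt <- step$state
    if (!is.finite(fw$loss$val[1])) stop("fine-tuning loss diverged (NaN)")
    logRow("finetune", ep, fw, nrow(centroids), NA_real_,
           if (!is.null(trueLabels)) {
             clusterARI(trueLabels, max.col(fw$Q$val, ties.method = "first"))
           } else NA_real_)
  }

  fw <- modelForward(params, data, cfg, noiseOn = FALSE, centroids = centroids)
  Q <- fw$Q$val
  labels <- max.col(Q, ties.method = "first")
  labels <- as.integer(factor(labels))
  methods::new("ScfFit",
               labels = labels, embedding = fw$R2$val, centroids = centroids,
               Q = Q, history = do.call(rbind, hist), kInit = as.integer(kInit),
               config = cfg)
}

#' One-call pipeline: preprocess, train, evaluate
#'
#' @param counts cells-by-genes count matrix or `SingleCellExperiment` (its
#'   `colData$cluster`, when present, is used as ground truth for evaluation
#'   only).
#' @param config list from [scfConfig()].
#' @param trueLabels optional ground-truth labels (overrides any carried by
#'   `counts`).
#' @param verbose passed to [scfTrain()].
#' @return list with `fit` (a [ScfFit-class]), `prep`
#'   (a [ScfPreprocessed-class]), and `metrics` (ARI/NMI/silhouette when
#'   ground truth is available, silhouette alone otherwise).
#' @export
scfPipeline <- function(counts, config = scfConfig(), trueLabels = NULL,
                        verbose = FALSE) {
  if (is.null(trueLabels) && methods::is(counts, "SingleCellExperiment") &&
      "cluster" %in% names(SummarizedExperiment::colData(counts))) {
    trueLabels <- counts$cluster
  }
  X <- asCellMatrix(counts)
  keepCells <- rowSums(X) > 0
  if (!is.null(trueLabels)) trueLabels <- trueLabels[keepCells]
  prep <- preprocessCounts(X, nHVG = config$nHVG, k = config$kNeighbors,
                           flavor = config$hvgFlavor,
                           sigmaMode = config$sigmaMode,
                           binarize = config$binarize,
                           targetSum = config$targetSum)
  fit <- scfTrain(prep, config, trueLabels = trueLabels, verbose = verbose)
  metrics <- list()
  if (nrow(fit@centroids) >= 2L) {
    metrics$silhouette <- silhouetteScore(fit@embedding, fit@labels)
  }
  if (!is.null(trueLabels)) {
    metrics$ari <- clusterARI(trueLabels, fit@labels)
    metrics$nmi <- clusterNMI(trueLabels, fit@labels)
  }
  list(fit = fit, prep = prep, metrics = metrics)
}
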