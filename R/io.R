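## File I/O: 10x-style MTX triplets, dense CSV/TSV, label tables, and the
## provenance sidecar written next to simulated data.

#' Read a count matrix from disk
#'
#' Accepts either a directory holding a Matrix Market triplet
#' (`matrix.mtx`, `barcodes.tsv`, `features.tsv` — genes in MTX rows, the
#' 10x convention) or a single dense CSV/TSV file with cells in rows, gene
#' names in the header, and cell identifiers in the first column.
#'
#' @param path directory (MTX triplet) or file (CSV/TSV).
#' @return dense cells-by-genes numeric matrix with dimnames.
#' @export
readCounts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    M <- as.matrix(Matrix::readMM(mtx))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    features <- utils::read.delim(file.path(path, "features.tsv"),
                                  header = FALSE)[[1L]]
    if (length(features) != nrow(M) || length(barcodes) != ncol(M)) {
      stop("barcodes/features do not match the matrix dimensions")
    }
    X <- t(M)
    dimnames(X) <- list(barcodes, features)
    return(X)
  }
  if (!file.exists(path)) stop("path does not exist: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("non-numeric entries in ", path)
  if (max(abs(X - round(X))) > 1e-6) {
    warning("counts are not integer-valued; proceeding with rounded checks off")
  }
  X
}

#' Write a count matrix (and labels) as an MTX triplet
#'
#' Writes `matrix.mtx` (genes in rows), `barcodes.tsv`, `features.tsv`, and,
#' when labels are present, `labels.tsv` (cell_id, cluster). A `sim.json`
#' sidecar records the provenance metadata passed in `meta`.
#'
#' @param x cells-by-genes matrix or a `SingleCellExperiment` (labels taken
#'   from `colData$cluster`).
#' @param dir output directory, created if needed.
#' @param labels optional label vector (overrides labels carried by `x`).
#' @param meta optional named list echoed into `sim.json`.
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(x, dir, labels = NULL, meta = NULL) {
  if (is.null(labels) && methods::is(x, "SingleCellExperiment") &&
      "cluster" %in% names(SummarizedExperiment::colData(x))) {
    labels <- x$cluster
  }
  X <- asCellMatrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(X), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  cells <- if (!is.null(rownames(X))) rownames(X) else
    sprintf("cell%04d", seq_len(nrow(X)))
  genes <- if (!is.null(colnames(X))) colnames(X) else
    sprintf("gene%04d", seq_len(ncol(X)))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  writeLines(genes, file.path(dir, "features.tsv"))
  if (!is.null(labels)) {
    utils::write.table(data.frame(cell_id = cells, cluster = labels),
                       file.path(dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(meta)) {
    jsonlite::write_json(meta, file.path(dir, "sim.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Write a dense CSV of counts
#'
#' @param x cells-by-genes matrix or `SingleCellExperiment`.
#' @param file output CSV path (cells in rows).
#' @return `file`, invisibly.
#' @export
writeCountsCSV <- function(x, file) {
  X <- asCellMatrix(x)
  utils::write.csv(as.data.frame(X), file, row.names = TRUE, quote = FALSE)
  invisible(file)
}

#' Write the artifacts of a fitted model to a run directory
#'
#' Emits `labels.tsv` (cell_id, cluster), `embedding.csv`, `history.jsonl`
#' (one JSON object per logged epoch), and `config.json` (the resolved
#' configuration and seed) — enough metadata to reproduce the run.
#'
#' @param fit a [ScfFit-class].
#' @param prep the matching [ScfPreprocessed-class] (for cell identifiers).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeRun <- function(fit, prep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(cell_id = prep@cellIds, cluster = fit@labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  emb <- as.data.frame(fit@embedding)
  rownames(emb) <- prep@cellIds
  utils::write.csv(emb, file.path(dir, "embedding.csv"), quote = FALSE)
  h <- fit@history
  con <- file(file.path(dir, "history.jsonl"), "w")
  for (i in seq_len(nrow(h))) {
    writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  }
  close(con)
  jsonlite::write_json(fit@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' Keys must match [scfConfig()] arguments; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readScfConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(scfConfig, vals)
}
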