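#' Construct a gene-by-barcode count matrix
#'
#' Thin container for sparse non-negative integer UMI counts with unique gene
#' and barcode identifiers and a dataset label (e.g. `"PBS7d"`). Counts are
#' stored as a `Matrix::dgCMatrix` with genes as rows, the 10x convention.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   genes as rows. Row and column names are taken as gene/barcode ids unless
#'   `genes`/`barcodes` are given.
#' @param dataset single dataset label.
#' @param genes,barcodes optional identifier vectors overriding dimnames.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `genes`, `barcodes`, `dataset`.
#' @export
count_matrix <- function(counts, dataset = "dataset", genes = NULL, barcodes = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (!methods::is(counts, "generalMatrix"))
    counts <- methods::as(counts, "generalMatrix")
  counts <- methods::as(counts, "CsparseMatrix")
  if (!methods::is(counts, "dMatrix")) counts <- counts * 1  # pattern -> numeric
  if (!is.null(genes)) rownames(counts) <- genes
  if (!is.null(barcodes)) colnames(counts) <- barcodes
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix requires gene and barcode identifiers")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate barcode identifiers")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  structure(
    list(counts = counts, genes = rownames(counts),
         barcodes = colnames(counts), dataset = as.character(dataset)[1]),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix '%s': %d genes x %d barcodes (%d nonzero)\n",
              x$dataset, length(x$genes), length(x$barcodes),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a barcode set
#'
#' @param x a [count_matrix()].
#' @param barcodes character vector of barcodes to retain (order preserved).
#' @return A `count_matrix` restricted to `barcodes`.
#' @export
subset_barcodes <- function(x, barcodes) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(barcodes, x$barcodes)
  if (length(missing))
    stop("barcodes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  count_matrix(x$counts[, barcodes, drop = FALSE], dataset = x$dataset)
}

#' Read a 10x-style triplet directory
#'
#' Reads `matrix.mtx` (MatrixMarket coordinate, 1-based, genes as rows),
#' `features.tsv` (gene ids in the first column) and `barcodes.tsv` from
#' `path`. Gzipped variants (`.gz`) are accepted.
#'
#' @param path directory containing the three files.
#' @param dataset dataset label; defaults to the directory name.
#' @return A [count_matrix()].
#' @export
read_10x <- function(path, dataset = basename(normalizePath(path, mustWork = FALSE))) {
  find1 <- function(stem) {
    for (f in file.path(path, c(stem, paste0(stem, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", stem, " in ", path)
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  feats <- utils::read.table(find1("features.tsv"), sep = "\t",
                             header = FALSE, colClasses = "character", quote = "")
  bcs <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                           header = FALSE, colClasses = "character", quote = "")
  if (nrow(feats) != nrow(m) || nrow(bcs) != ncol(m))
    stop("dimension mismatch between matrix and features/barcodes files")
  count_matrix(m, dataset = dataset, genes = feats[[1]], barcodes = bcs[[1]])
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' Inverse of [read_10x()]: emits `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` (uncompressed) under `path`.
#'
#' @param x a [count_matrix()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_10x <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(x$genes, file.path(path, "features.tsv"))
  writeLines(x$barcodes, file.path(path, "barcodes.tsv"))
  invisible(path)
}
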