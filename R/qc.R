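#' Identify mitochondrial genes
#'
#' Mitochondrial genes are matched by name prefix (default `"mt-"`,
#' case-insensitive) unless an explicit list is given.
#'
#' @param genes character vector of gene identifiers.
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @param mito_genes optional explicit gene list overriding the prefix rule.
#' @return Character vector of mitochondrial gene ids present in `genes`.
#' @export
mito_gene_set <- function(genes, mito_prefix = "mt-", mito_genes = NULL) {
  if (!is.null(mito_genes)) {
    missing <- setdiff(mito_genes, genes)
    if (length(missing))
      warning(length(missing), " mitochondrial gene(s) absent from matrix")
    return(intersect(mito_genes, genes))
  }
  genes[startsWith(tolower(genes), tolower(mito_prefix))]
}

#' Per-barcode quality-control metrics
#'
#' Computes, for every barcode: total UMI count (`n_umi`), number of detected
#' genes (`n_genes`), the complexity metric
#' `log10_genes_per_umi = log10(n_genes) / log10(n_umi)`, and the fraction of
#' UMIs from mitochondrial genes (`mito_ratio`). The log-ratio is undefined
#' (NA) when `n_umi <= 1`; such barcodes are reported, never dropped.
#' `mito_ratio` is defined as 0 for an all-zero barcode.
#'
#' @param x a [count_matrix()].
#' @param mito_genes explicit mitochondrial gene list; if `NULL`, genes
#'   matching `mito_prefix` are used.
#' @param mito_prefix name prefix identifying mitochondrial genes.
#' @return A data.frame with one row per barcode: `barcode`, `n_umi`,
#'   `n_genes`, `log10_genes_per_umi`, `mito_ratio`.
#' @export
compute_cell_qc <- function(x, mito_genes = NULL, mito_prefix = "mt-") {
  stopifnot(inherits(x, "count_matrix"))
  mito <- mito_gene_set(x$genes, mito_prefix, mito_genes)
  n_umi <- Matrix::colSums(x$counts)
  n_genes <- Matrix::colSums(x$counts > 0)
  mito_umi <- if (length(mito)) Matrix::colSums(x$counts[mito, , drop = FALSE]) else 0
  log_ratio <- ifelse(n_umi > 1, log10(pmax(n_genes, 1)) / log10(n_umi), NA_real_)
  data.frame(
    barcode = x$barcodes,
    n_umi = as.numeric(n_umi),
    n_genes = as.integer(n_genes),
    log10_genes_per_umi = as.numeric(log_ratio),
    mito_ratio = ifelse(n_umi > 0, mito_umi / pmax(n_umi, 1), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Barcode-level QC thresholds
#'
#' All four comparisons are strict: a barcode is retained only if
#' `n_umi > min_umi`, `n_genes > min_genes`,
#' `log10_genes_per_umi > min_log_ratio` and `mito_ratio < max_mito`.
#' Boundary cells are rejected.
#'
#' @param min_umi exclusive lower bound on total UMIs (default 400).
#' @param min_genes exclusive lower bound on detected genes (default 200).
#' @param min_log_ratio exclusive lower bound on log10 genes per UMI
#'   (default 0.8).
#' @param max_mito exclusive upper bound on mitochondrial UMI fraction
#'   (default 0.23).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 400, min_genes = 200,
                          min_log_ratio = 0.8, max_mito = 0.23) {
  stopifnot(is.finite(min_umi), is.finite(min_genes), is.finite(min_log_ratio),
            is.finite(max_mito), max_mito > 0, max_mito < 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 min_log_ratio = min_log_ratio, max_mito = max_mito),
            class = "qc_thresholds")
}

#' Apply the four-rule barcode QC filter
#'
#' A barcode passes only if it clears all four strict thresholds (see
#' [qc_thresholds()]). Barcodes with an undefined log-ratio (`n_umi <= 1`)
#' fail the log-ratio rule by definition.
#'
#' @param metrics data.frame from [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with `retained` (character vector of barcodes passing all
#'   rules) and `report` (data.frame of per-rule failure counts plus totals).
#' @export
apply_qc_filter <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            all(c("barcode", "n_umi", "n_genes",
                  "log10_genes_per_umi", "mito_ratio") %in% names(metrics)))
  pass_umi <- metrics$n_umi > thresholds$min_umi
  pass_genes <- metrics$n_genes > thresholds$min_genes
  lr <- metrics$log10_genes_per_umi
  pass_lr <- !is.na(lr) & lr > thresholds$min_log_ratio
  pass_mito <- metrics$mito_ratio < thresholds$max_mito
  keep <- pass_umi & pass_genes & pass_lr & pass_mito
  report <- data.frame(
    rule = c("n_umi", "n_genes", "log10_genes_per_umi", "mito_ratio",
             "any_rule", "retained"),
    n_failed = c(sum(!pass_umi), sum(!pass_genes), sum(!pass_lr),
                 sum(!pass_mito), sum(!keep), NA_integer_),
    n_barcodes = nrow(metrics),
    stringsAsFactors = FALSE)
  report$n_failed[report$rule == "retained"] <- sum(keep)
  list(retained = metrics$barcode[keep], report = report)
}

#' Run QC end-to-end on a count matrix
#'
#' Convenience wrapper: computes metrics, applies the filter, and returns the
#' filtered matrix together with the metrics and report.
#'
#' @inheritParams compute_cell_qc
#' @inheritParams apply_qc_filter
#' @return List with `matrix` (filtered [count_matrix()]), `metrics`,
#'   `retained`, `report`.
#' @export
qc_filter_matrix <- function(x, thresholds = qc_thresholds(),
                             mito_genes = NULL, mito_prefix = "mt-") {
  metrics <- compute_cell_qc(x, mito_genes = mito_genes, mito_prefix = mito_prefix)
  res <- apply_qc_filter(metrics, thresholds)
  list(matrix = subset_barcodes(x, res$retained),
       metrics = metrics, retained = res$retained, report = res$report)
}
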