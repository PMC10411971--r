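#' Aggregate single-cell counts into per-group pseudobulk profiles
#'
#' Pools cells by the grouping columns of the annotation (default cluster x
#' dataset) and records, per gene and group, the summed raw counts
#' (`raw_sum`) and the un-normalized mean over the group's cells
#' (`raw_mean = raw_sum / n_cells`). Groups with zero cells are omitted.
#'
#' @param x a [count_matrix()], or a list of them (datasets are concatenated;
#'   gene universes must match).
#' @param ann annotation data.frame with a `barcode` column and the grouping
#'   columns; every matrix barcode must be annotated exactly once.
#' @param groupby character vector of annotation columns defining groups.
#' @return An object of class `pseudobulk`: list with `genes`, `groups`
#'   (data.frame with the grouping columns plus `group`, `n_cells`,
#'   `total_counts`), and matrices `raw_sum`, `raw_mean` (genes x groups);
#'   `norm` is added by [normalize_pseudobulk()].
#' @export
aggregate_pseudobulk <- function(x, ann, groupby = c("cluster", "dataset")) {
  if (inherits(x, "count_matrix")) {
    counts <- x$counts
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "count_matrix"))) {
    universes <- unique(lapply(x, `[[`, "genes"))
    if (length(universes) != 1) stop("gene universes differ across matrices")
    counts <- do.call(cbind, lapply(x, `[[`, "counts"))
  } else stop("x must be a count_matrix or a list of them")
  stopifnot("barcode" %in% names(ann), all(groupby %in% names(ann)))
  if (anyDuplicated(ann$barcode)) stop("duplicate barcodes in annotation")
  missing <- setdiff(ann$barcode, colnames(counts))
  if (length(missing))
    stop("annotation references barcodes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  unannotated <- setdiff(colnames(counts), ann$barcode)
  if (length(unannotated))
    stop(length(unannotated), " barcode(s) in matrix lack annotation")
  ann <- ann[match(colnames(counts), ann$barcode), , drop = FALSE]

  key <- interaction(ann[groupby], sep = "|", drop = TRUE, lex.order = TRUE)
  levels_key <- levels(key)
  # sparse indicator: cells x groups; crossprod gives per-group gene sums
  ind <- Matrix::sparseMatrix(
    i = seq_along(key), j = as.integer(key), x = 1,
    dims = c(length(key), length(levels_key)))
  raw_sum <- as.matrix(counts %*% ind)
  colnames(raw_sum) <- levels_key
  n_cells <- as.integer(table(key))
  raw_mean <- sweep(raw_sum, 2, n_cells, "/")

  parts <- do.call(rbind, strsplit(levels_key, "|", fixed = TRUE))
  groups <- data.frame(parts, stringsAsFactors = FALSE)
  names(groups) <- groupby
  groups$group <- levels_key
  groups$n_cells <- n_cells
  groups$total_counts <- colSums(raw_sum)
  structure(list(genes = rownames(counts), groupby = groupby, groups = groups,
                 raw_sum = raw_sum, raw_mean = raw_mean),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d groups (by %s)%s\n",
              length(x$genes), nrow(x$groups), paste(x$groupby, collapse = " x "),
              if (is.null(x$norm)) "" else "; normalized"))
  invisible(x)
}

#' Library-size normalize a pseudobulk table
#'
#' Adds a `norm` layer: `norm[g, grp] = scale * raw_sum[g, grp] /
#' total_counts[grp]`, so each group's normalized column sums to `scale`
#' (counts-per-million by default). Cell-number normalization enters through
#' the `raw_mean` layer; this step removes per-group sequencing depth.
#'
#' @param pb a `pseudobulk` object from [aggregate_pseudobulk()].
#' @param scale positive scaling constant (default `1e6`).
#' @return `pb` with a `norm` layer added.
#' @export
normalize_pseudobulk <- function(pb, scale = 1e6) {
  stopifnot(inherits(pb, "pseudobulk"), scale > 0)
  zero <- pb$groups$total_counts <= 0
  if (any(zero))
    stop("group(s) with zero total counts: ",
         paste(pb$groups$group[zero], collapse = ", "))
  pb$norm <- sweep(pb$raw_sum, 2, pb$groups$total_counts, "/") * scale
  pb$scale <- scale
  pb
}

#' Upper-quartile scaling factors
#'
#' Computes, per sample (column), the 75th percentile (linear interpolation)
#' of its nonzero values, and returns factors `UQ_s / geometric-mean(UQ)`;
#' dividing each sample by its factor equalizes upper quartiles across
#' samples.
#'
#' @param x numeric matrix, genes x samples, non-negative.
#' @param probs quantile to equalize (default 0.75).
#' @return Named numeric vector of per-sample factors.
#' @export
upper_quartile_factors <- function(x, probs = 0.75) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative expression values")
  uq <- apply(x, 2, uq_nonzero, probs = probs)
  if (anyNA(uq)) stop("all-zero sample(s): ",
                      paste(colnames(x)[is.na(uq)], collapse = ", "))
  uq / exp(mean(log(uq)))
}

#' Average expression reference by cluster and timepoint
#'
#' Mean raw counts per gene across all cells of each cluster at each
#' timepoint, pooled over conditions — the query reference profile.
#'
#' @inheritParams aggregate_pseudobulk
#' @return A `pseudobulk` object grouped by `(cluster, timepoint)`.
#' @export
average_expression_reference <- function(x, ann) {
  aggregate_pseudobulk(x, ann, groupby = c("cluster", "timepoint"))
}

#' Cluster marker genes by rank-sum test
#'
#' Candidate genes must be detected (count > 0) in at least `min_detection`
#' of the cluster's cells. Each candidate is tested cluster-vs-rest with a
#' two-sided Wilcoxon rank-sum test; p-values are Bonferroni-adjusted over
#' the tested genes and markers retained at adjusted p < `alpha`, ranked by
#' average log2 fold change then p-value.
#'
#' @param x a [count_matrix()].
#' @param ann annotation data.frame with `barcode` and `cluster` columns.
#' @param cluster cluster to profile (must have >= 3 cells).
#' @param min_detection minimum detection fraction within the cluster
#'   (default 0.25).
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @param pseudocount added to group means for the fold-change estimate.
#' @return data.frame: `gene`, `detection_frac`, `avg_log2FC`, `p_value`,
#'   `p_adj`, `marker` (logical), sorted by `avg_log2FC` desc then `p_adj`.
#' @export
marker_genes <- function(x, ann, cluster, min_detection = 0.25, alpha = 0.05,
                         pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  ann <- ann[match(x$barcodes, ann$barcode), , drop = FALSE]
  in_cl <- !is.na(ann$cluster) & ann$cluster == cluster
  if (!any(in_cl)) stop("cluster absent from annotation: ", cluster)
  if (sum(in_cl) < 3) stop("cluster has fewer than 3 cells")
  counts <- x$counts
  det <- Matrix::rowSums(counts[, in_cl, drop = FALSE] > 0) / sum(in_cl)
  candidates <- which(det >= min_detection)
  if (!length(candidates))
    return(data.frame(gene = character(), detection_frac = numeric(),
                      avg_log2FC = numeric(), p_value = numeric(),
                      p_adj = numeric(), marker = logical()))
  sub <- as.matrix(counts[candidates, , drop = FALSE])
  mean_in <- rowMeans(sub[, in_cl, drop = FALSE])
  mean_out <- rowMeans(sub[, !in_cl, drop = FALSE])
  pvals <- vapply(seq_len(nrow(sub)), function(i)
    stats::wilcox.test(sub[i, in_cl], sub[i, !in_cl], exact = FALSE)$p.value,
    numeric(1))
  res <- data.frame(
    gene = rownames(sub),
    detection_frac = as.numeric(det[candidates]),
    avg_log2FC = log2((mean_in + pseudocount) / (mean_out + pseudocount)),
    p_value = pvals,
    p_adj = pmin(1, pvals * length(pvals)),  # Bonferroni over tested genes
    stringsAsFactors = FALSE)
  res$marker <- res$p_adj < alpha
  res[order(-res$avg_log2FC, res$p_adj, res$gene), , drop = FALSE]
}

#' Write a pseudobulk layer to TSV
#'
#' @param pb a `pseudobulk` object.
#' @param path output file.
#' @param layer one of `"raw_mean"`, `"raw_sum"`, `"norm"`.
#' @return `path`, invisibly.
#' @export
write_pseudobulk <- function(pb, path, layer = c("norm", "raw_mean", "raw_sum")) {
  layer <- match.arg(layer)
  mat <- pb[[layer]]
  if (is.null(mat)) stop("layer not present: ", layer)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# layer: ", layer), con)
  utils::write.table(data.frame(gene = pb$genes, mat, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
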