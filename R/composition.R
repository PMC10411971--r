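#' Per-dataset cluster proportions
#'
#' Counts annotated cells per (cluster, dataset) and divides by the
#' dataset's total; clusters from the universe absent in a dataset are
#' reported with zero cells.
#'
#' @param ann annotation data.frame with `cluster` and `dataset` columns.
#' @param universe cluster set to report; defaults to the clusters observed
#'   anywhere in `ann`. Every annotated cell must map into it.
#' @return data.frame: `cluster`, `dataset`, `n_cells`, `proportion`; within
#'   each dataset the proportions sum to 1.
#' @export
cluster_proportions <- function(ann, universe = NULL) {
  stopifnot(all(c("cluster", "dataset") %in% names(ann)), nrow(ann) > 0)
  if (is.null(universe)) universe <- sort(unique(ann$cluster))
  bad <- setdiff(unique(ann$cluster), universe)
  if (length(bad)) stop("annotated cluster(s) outside universe: ",
                        paste(bad, collapse = ", "))
  datasets <- unique(ann$dataset)
  tab <- table(factor(ann$cluster, levels = universe),
               factor(ann$dataset, levels = datasets))
  totals <- colSums(tab)
  if (any(totals == 0)) stop("dataset with zero cells")
  out <- expand.grid(cluster = universe, dataset = datasets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_cells <- as.integer(tab[cbind(out$cluster, out$dataset)])
  out$proportion <- out$n_cells / totals[out$dataset]
  rownames(out) <- NULL
  out
}

#' Log2 cluster-proportion ratio between conditions
#'
#' For each cluster, compares its share of cells under condition A versus
#' condition B:
#' `log2(((n_a + pc) / (N_a + pc)) / ((n_b + pc) / (N_b + pc)))`, a
#' continuity-corrected (Haldane-Anscombe-style) ratio in which `pc` is
#' applied to counts, keeping ratios finite for clusters that vanish in one
#' condition. Clusters with a positive ratio are labeled as associated with
#' condition A (e.g. regenerative under PBS), negative with condition B
#' (macrophage-delayed under CL).
#'
#' @param ann annotation data.frame with `cluster`, `condition`, `timepoint`,
#'   `dataset` columns.
#' @param cond_a,cond_b condition labels to contrast (default PBS vs CL).
#' @param pool timepoint policy: `"injured"` pools timepoints > 0 per
#'   condition, `"all"` pools everything, `"per_timepoint"` returns one row
#'   per cluster x shared timepoint.
#' @param pseudocount continuity correction added to numerator and
#'   denominator counts (default 0.5).
#' @param universe cluster set to report (default: clusters observed in the
#'   contrasted conditions).
#' @param neutral_band |ratio| at or below which a cluster is labeled
#'   `neutral` (default 0).
#' @return data.frame: `cluster` (and `timepoint` in per-timepoint mode),
#'   `n_a`, `N_a`, `n_b`, `N_b`, `log2_ratio`, `association` with levels
#'   `cond_a` / `cond_b` / `"neutral"`.
#' @export
log2_condition_ratio <- function(ann, cond_a = "PBS", cond_b = "CL",
                                 pool = c("injured", "all", "per_timepoint"),
                                 pseudocount = 0.5, universe = NULL,
                                 neutral_band = 0) {
  pool <- match.arg(pool)
  stopifnot(all(c("cluster", "condition", "timepoint") %in% names(ann)),
            pseudocount >= 0)
  sub <- ann[ann$condition %in% c(cond_a, cond_b), , drop = FALSE]
  if (pool == "injured") sub <- sub[sub$timepoint > 0, , drop = FALSE]
  for (cc in c(cond_a, cond_b))
    if (!any(sub$condition == cc)) stop("condition with zero cells: ", cc)
  if (is.null(universe)) universe <- sort(unique(sub$cluster))

  one_contrast <- function(d) {
    na <- table(factor(d$cluster[d$condition == cond_a], levels = universe))
    nb <- table(factor(d$cluster[d$condition == cond_b], levels = universe))
    Na <- sum(na); Nb <- sum(nb)
    if (Na == 0 || Nb == 0) stop("condition with zero cells in stratum")
    # difference of logs, so swapping the conditions negates ratios exactly
    ratio <- log2((as.numeric(na) + pseudocount) / (Na + pseudocount)) -
             log2((as.numeric(nb) + pseudocount) / (Nb + pseudocount))
    data.frame(cluster = universe,
               n_a = as.integer(na), N_a = Na,
               n_b = as.integer(nb), N_b = Nb,
               log2_ratio = ratio,
               association = ifelse(ratio > neutral_band, cond_a,
                                    ifelse(ratio < -neutral_band, cond_b, "neutral")),
               stringsAsFactors = FALSE)
  }
  if (pool == "per_timepoint") {
    tps <- sort(intersect(unique(sub$timepoint[sub$condition == cond_a]),
                          unique(sub$timepoint[sub$condition == cond_b])))
    out <- do.call(rbind, lapply(tps, function(tp) {
      r <- one_contrast(sub[sub$timepoint == tp, , drop = FALSE])
      cbind(timepoint = tp, r)
    }))
    rownames(out) <- NULL
    out
  } else one_contrast(sub)
}

#' Stacked composition percentages over datasets
#'
#' Wide table of cluster percentages (columns per dataset, summing to 100)
#' for stacked-bar composition displays over the timecourse.
#'
#' @param prop_table output of [cluster_proportions()].
#' @param datasets column order; default order of appearance.
#' @return data.frame: `cluster` plus one percentage column per dataset.
#' @export
composition_timecourse <- function(prop_table, datasets = unique(prop_table$dataset)) {
  stopifnot(all(c("cluster", "dataset", "proportion") %in% names(prop_table)))
  clusters <- unique(prop_table$cluster)
  out <- data.frame(cluster = clusters, stringsAsFactors = FALSE)
  for (d in datasets) {
    sub <- prop_table[prop_table$dataset == d, ]
    out[[d]] <- 100 * sub$proportion[match(clusters, sub$cluster)]
  }
  out
}
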