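#' Pipeline configuration
#'
#' Bundles a simulation config (or paths to existing 10x directories) with
#' the parameters of every downstream stage.
#'
#' @param sim a [sim_config()] describing the datasets to generate, or
#'   `NULL` when `input_dirs` is given.
#' @param input_dirs named character vector (dataset id -> 10x directory);
#'   requires `annotation_path`.
#' @param annotation_path TSV with columns `barcode`, `cluster`,
#'   `condition`, `timepoint`, `dataset` (needed only with `input_dirs`).
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix mitochondrial gene-name prefix for QC.
#' @param de list of M-D parameters: `k`, `pnr`, `nss`, `nv`, `q_threshold`.
#' @param composition list: `cond_a`, `cond_b`, `pool`, `pseudocount`.
#' @param crosstalk list: `senders`, `receivers`, `timepoint`, `quantile`.
#'   Ligand-receptor enumeration runs in both directions
#'   (senders -> receivers and receivers -> senders).
#' @param lr_pairs optional ligand-receptor database data.frame (`ligand`,
#'   `receptor`); defaults to the simulation's planted + decoy pairs.
#' @param seed integer seed controlling every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = default_sim_config(),
                            input_dirs = NULL, annotation_path = NULL,
                            thresholds = qc_thresholds(),
                            mito_prefix = "mt-",
                            de = list(k = 0.5, pnr = 0.2, nss = 5, nv = 0.02,
                                      q_threshold = 0.8),
                            composition = list(cond_a = "PBS", cond_b = "CL",
                                               pool = "injured", pseudocount = 0.5),
                            crosstalk = list(senders = c(paste0("Mac", 1:9), "MN"),
                                             receivers = c("Neu1", "Neu2"),
                                             timepoint = 7, quantile = 0.75),
                            lr_pairs = NULL,
                            seed = 1L) {
  if (is.null(sim) && is.null(input_dirs))
    stop("either a simulation config or input directories are required")
  if (!is.null(input_dirs) && is.null(annotation_path))
    stop("input_dirs requires annotation_path")
  structure(list(sim = sim, input_dirs = input_dirs,
                 annotation_path = annotation_path,
                 thresholds = thresholds, mito_prefix = mito_prefix,
                 de = de, composition = composition, crosstalk = crosstalk,
                 lr_pairs = lr_pairs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] /
#' [default_sim_config()] arguments; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "n_genes", "n_cells", "n_planted_deg", "n_planted_lr",
             "n_decoy_lr", "nb_dispersion", "mito_frac", "qc", "de",
             "composition", "crosstalk")
  if (length(bad <- setdiff(names(y), known)))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(y$seed %||% 1L)
  sim_args <- y[intersect(names(y), c("n_genes", "n_cells", "n_planted_deg",
                                      "n_planted_lr", "n_decoy_lr",
                                      "nb_dispersion", "mito_frac"))]
  sim <- do.call(default_sim_config, c(list(seed = seed), sim_args))
  args <- list(sim = sim, seed = seed)
  if (!is.null(y$qc)) args$thresholds <- do.call(qc_thresholds, y$qc)
  defaults <- formals(pipeline_config)
  for (part in c("de", "composition", "crosstalk")) {
    if (is.null(y[[part]])) next
    merged <- eval(defaults[[part]])
    merged[names(y[[part]])] <- y[[part]]
    args[[part]] <- merged
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparative pipeline
#'
#' Executes generate (or load) -> QC -> pseudobulk -> per-cluster M-D
#' differential expression -> composition -> crosstalk, writing every stage's
#' outputs under `out_dir` plus a `manifest.json` of relative paths and MD5
#' hashes. Identical config + seed yields byte-identical outputs and
#' manifest. When ground truth is available (simulated input), a
#' truth-vs-result evaluation (planted gene recovery, ligand-receptor
#' precision/recall) is emitted as `evaluation.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return The manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(pipeline = "cardiocomm", seed = config$seed, stages = list())
  outputs <- character()
  note <- function(...) outputs <<- c(outputs, file.path(...))

  ## stage 1: simulate or load -------------------------------------------
  if (!is.null(config$sim)) {
    sims <- generate_all_datasets(config$sim)
    matrices <- lapply(sims, `[[`, "matrix")
    annotation <- do.call(rbind, lapply(sims, `[[`, "annotation"))
    rownames(annotation) <- NULL
    for (d in names(sims)) {
      write_10x(matrices[[d]], file.path(out_dir, "counts", d))
      note("counts", d, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
      write_truth(sims[[d]]$truth, file.path(out_dir, "truth", d))
      note("truth", d, c("cluster_assignments.tsv", "deg_truth.tsv",
                         "lr_truth.tsv", "cluster_counts.tsv", "dataset.txt"))
    }
    write_tsv(annotation, file.path(out_dir, "annotation.tsv"))
    note("annotation.tsv")
    truth <- list(planted_degs = config$sim$planted_degs,
                  planted_lr = config$sim$planted_lr)
    stage1 <- "simulate"
  } else {
    matrices <- lapply(names(config$input_dirs), function(d)
      read_10x(config$input_dirs[[d]], dataset = d))
    names(matrices) <- names(config$input_dirs)
    annotation <- read_tsv(config$annotation_path)
    truth <- NULL
    stage1 <- "load"
  }
  manifest$stages[[stage1]] <- list(datasets = names(matrices))

  ## stage 2: QC ----------------------------------------------------------
  qc_reports <- list()
  for (d in names(matrices)) {
    res <- qc_filter_matrix(matrices[[d]], config$thresholds,
                            mito_prefix = config$mito_prefix)
    matrices[[d]] <- res$matrix
    rep_d <- res$report; rep_d$dataset <- d
    qc_reports[[d]] <- rep_d
  }
  qc_report <- do.call(rbind, c(qc_reports, list(make.row.names = FALSE)))
  write_tsv(qc_report, file.path(out_dir, "qc_report.tsv"))
  note("qc_report.tsv")
  retained <- unlist(lapply(matrices, `[[`, "barcodes"), use.names = FALSE)
  annotation <- annotation[annotation$barcode %in% retained, , drop = FALSE]
  write_tsv(annotation, file.path(out_dir, "annotation_qc.tsv"))
  note("annotation_qc.tsv")
  manifest$stages$qc <- list(
    thresholds = unclass(config$thresholds),
    n_retained = length(retained))

  ## stage 3: pseudobulk --------------------------------------------------
  pb <- aggregate_pseudobulk(matrices, annotation,
                             groupby = c("cluster", "dataset"))
  pb <- normalize_pseudobulk(pb)
  write_pseudobulk(pb, file.path(out_dir, "pseudobulk_norm.tsv"), "norm")
  write_pseudobulk(pb, file.path(out_dir, "pseudobulk_raw_mean.tsv"), "raw_mean")
  note(c("pseudobulk_norm.tsv", "pseudobulk_raw_mean.tsv"))
  manifest$stages$pseudobulk <- list(n_groups = nrow(pb$groups))

  ## stage 4: differential expression ------------------------------------
  cc <- config$composition
  dsets <- unique(annotation[c("dataset", "condition")])
  ds_a <- dsets$dataset[dsets$condition == cc$cond_a]
  ds_b <- dsets$dataset[dsets$condition == cc$cond_b]
  de <- config$de
  de_tables <- pseudobulk_de(pb, ds_a, ds_b,
                             q_threshold = de$q_threshold, k = de$k,
                             pnr = de$pnr, nss = de$nss, nv = de$nv,
                             seed = derive_seed(config$seed, 40))
  de_all <- do.call(rbind, lapply(names(de_tables), function(cl) {
    t <- as.data.frame(de_tables[[cl]]); t$cluster <- cl; t
  }))
  rownames(de_all) <- NULL
  write_tsv(de_all, file.path(out_dir, "de_condition_enriched.tsv"))
  note("de_condition_enriched.tsv")
  manifest$stages$de <- list(
    contrast = paste(cc$cond_a, "vs", cc$cond_b),
    clusters = names(de_tables),
    n_called = sum(de_all$call))

  ## stage 5: composition -------------------------------------------------
  props <- cluster_proportions(annotation)
  write_tsv(props, file.path(out_dir, "composition_proportions.tsv"))
  tc <- composition_timecourse(props)
  write_tsv(tc, file.path(out_dir, "composition_timecourse.tsv"))
  ratios <- log2_condition_ratio(annotation, cc$cond_a, cc$cond_b,
                                 pool = cc$pool, pseudocount = cc$pseudocount)
  write_tsv(ratios, file.path(out_dir, "composition_log2_ratio.tsv"))
  note(c("composition_proportions.tsv", "composition_timecourse.tsv",
         "composition_log2_ratio.tsv"))
  manifest$stages$composition <- list(
    contrast = paste(cc$cond_a, "vs", cc$cond_b), pool = cc$pool)

  ## stage 6: crosstalk ---------------------------------------------------
  ct <- config$crosstalk
  db <- config$lr_pairs
  if (is.null(db)) {
    if (is.null(truth)) stop("no ligand-receptor database configured")
    db <- unique(rbind(truth$planted_lr[c("ligand", "receptor")],
                       config$sim$decoy_lr[c("ligand", "receptor")]))
  }
  ds_tp <- function(cond) {
    hit <- annotation$condition == cond &
      annotation$timepoint == ct$timepoint
    unique(annotation$dataset[hit])
  }
  da <- ds_tp(cc$cond_a); db_ds <- ds_tp(cc$cond_b)
  if (length(da) != 1 || length(db_ds) != 1)
    stop("crosstalk timepoint must select exactly one dataset per condition")
  edge_set <- function(dataset) {
    cl_here <- unique(annotation$cluster[annotation$dataset == dataset])
    clusters <- intersect(c(ct$senders, ct$receivers), cl_here)
    expr <- lapply(clusters, function(cl)
      expressed_genes(pb, cl, dataset, quantile = ct$quantile))
    names(expr) <- clusters
    s <- intersect(ct$senders, clusters); r <- intersect(ct$receivers, clusters)
    rbind(enumerate_interactions(db, expr, s, r, dataset),
          enumerate_interactions(db, expr, r, s, dataset))
  }
  edges_a <- edge_set(da); edges_b <- edge_set(db_ds)
  labeled <- condition_specific_pairs(edges_a, edges_b,
                                      label_a = cc$cond_a, label_b = cc$cond_b)
  utils::write.csv(labeled, file.path(out_dir, "crosstalk_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sif(labeled, file.path(out_dir, "crosstalk_edges.sif"))
  write_graphml(labeled, file.path(out_dir, "crosstalk_network.graphml"))
  note(c("crosstalk_edges.csv", "crosstalk_edges.sif", "crosstalk_network.graphml"))
  manifest$stages$crosstalk <- list(
    timepoint = ct$timepoint,
    n_edges = nrow(labeled),
    n_specific = sum(labeled$specificity != "shared"))

  ## stage 7: truth evaluation -------------------------------------------
  if (!is.null(truth)) {
    eval_res <- evaluate_against_truth(truth, de_tables, edges_a, edges_b,
                                       cond_a = cc$cond_a, cond_b = cc$cond_b)
    jsonlite::write_json(eval_res, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    note("evaluation.json")
    manifest$stages$evaluation <- eval_res[c("lr_precision", "lr_recall")]
  }

  ## manifest -------------------------------------------------------------
  manifest$outputs <- lapply(sort(outputs), function(p)
    list(path = p, md5 = unname(tools::md5sum(file.path(out_dir, p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Compare pipeline results with planted ground truth
#'
#' Planted-gene recovery: fraction of planted condition-enriched genes
#' called in their cluster with the correct sign. Ligand-receptor recovery
#' at the pair level: a pair is predicted condition-specific when it appears
#' in exactly one condition's network; precision/recall are computed against
#' the planted condition-specific pairs.
#'
#' @param truth list with `planted_degs` and `planted_lr`.
#' @param de_tables named list of `deg_table` per cluster (A vs B contrast).
#' @param edges_a,edges_b enumerated edges per condition.
#' @param cond_a,cond_b condition labels matching the truth's `condition`.
#' @return List of recovery metrics.
#' @export
evaluate_against_truth <- function(truth, de_tables, edges_a, edges_b,
                                   cond_a = "PBS", cond_b = "CL") {
  deg <- truth$planted_degs
  deg_hit <- logical(0)
  if (nrow(deg)) {
    deg_hit <- vapply(seq_len(nrow(deg)), function(i) {
      t <- de_tables[[deg$cluster[i]]]
      if (is.null(t)) return(NA)
      row <- t[t$gene == deg$gene[i], ]
      if (!nrow(row)) return(NA)
      want_pos <- deg$condition[i] == cond_a  # M = log2(a/b)
      row$call[1] && ((row$M[1] > 0) == want_pos)
    }, logical(1))
  }
  pair_id <- function(e) unique(paste(e$ligand, e$receptor, sep = "\r"))
  pa <- pair_id(edges_a); pb_ <- pair_id(edges_b)
  pred <- rbind(
    data.frame(pair = setdiff(pa, pb_), condition = cond_a),
    data.frame(pair = setdiff(pb_, pa), condition = cond_b))
  planted <- truth$planted_lr
  truth_pairs <- paste(paste(planted$ligand, planted$receptor, sep = "\r"),
                       planted$condition)
  pred_pairs <- paste(pred$pair, pred$condition)
  tp <- sum(pred_pairs %in% truth_pairs)
  list(
    n_planted_degs = nrow(deg),
    deg_recovery = if (length(deg_hit)) mean(deg_hit, na.rm = TRUE) else NA,
    n_planted_lr = nrow(planted),
    n_predicted_specific = nrow(pred),
    lr_true_positives = tp,
    lr_precision = if (nrow(pred)) tp / nrow(pred) else NA,
    lr_recall = if (nrow(planted)) tp / nrow(planted) else NA)
}
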