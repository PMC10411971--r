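#' Simulation configuration for multi-dataset single-cell counts
#'
#' Bundles everything needed to generate negative-binomial gene-by-barcode
#' count matrices for a panel of datasets (condition x timepoint) with known
#' ground truth: cluster mean-expression profiles, per-dataset cluster
#' proportions, planted condition-enriched genes, and planted
#' condition-specific ligand-receptor pairs.
#'
#' @param genes character vector of gene identifiers (unique).
#' @param clusters character vector of cluster names.
#' @param profiles numeric matrix (genes x clusters) of baseline negative
#'   binomial mean counts per cell.
#' @param datasets data.frame with columns `dataset`, `condition`,
#'   `timepoint`, `n_cells`.
#' @param proportions numeric matrix (datasets x clusters); each row a
#'   simplex over clusters.
#' @param planted_degs data.frame (`gene`, `cluster`, `condition`, `lfc`):
#'   in datasets of that condition, the gene's mean in that cluster is
#'   multiplied by `2^lfc`.
#' @param planted_lr data.frame (`ligand`, `receptor`, `sender`, `receiver`,
#'   `condition`): under that condition the ligand is highly expressed in the
#'   sender cluster and the receptor in the receiver cluster; both stay at
#'   their (low) baseline elsewhere.
#' @param decoy_lr data.frame (`ligand`, `receptor`) of non-condition-specific
#'   pairs carried along for crosstalk evaluation.
#' @param mito_genes subset of `genes` treated as mitochondrial.
#' @param nb_dispersion negative binomial dispersion phi (variance
#'   `mu + phi * mu^2`); must be > 0.
#' @param libsize_lognormal length-2 numeric `(meanlog, sdlog)` of the
#'   per-cell library-size factor.
#' @param lr_high mean count assigned to a planted ligand/receptor in its
#'   active cluster x condition.
#' @param seed integer base seed; per-dataset seeds are derived from it.
#' @return An object of class `sim_config`.
#' @seealso [default_sim_config()] for a ready-made configuration emulating
#'   the seven-dataset study design.
#' @export
sim_config <- function(genes, clusters, profiles, datasets, proportions,
                       planted_degs = empty_deg_table(),
                       planted_lr = empty_lr_table(),
                       decoy_lr = data.frame(ligand = character(), receptor = character()),
                       mito_genes = character(),
                       nb_dispersion = 0.1,
                       libsize_lognormal = c(0, 0.3),
                       lr_high = 20,
                       seed = 1L) {
  genes <- as.character(genes); clusters <- as.character(clusters)
  if (length(genes) < 1) stop("need at least one gene")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(clusters)) stop("duplicate cluster names")
  stopifnot(is.matrix(profiles), nrow(profiles) == length(genes),
            ncol(profiles) == length(clusters), all(profiles >= 0))
  rownames(profiles) <- genes; colnames(profiles) <- clusters
  stopifnot(all(c("dataset", "condition", "timepoint", "n_cells") %in% names(datasets)),
            !anyDuplicated(datasets$dataset), all(datasets$n_cells >= 1))
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions))) rownames(proportions) <- datasets$dataset
  stopifnot(identical(sort(rownames(proportions)), sort(as.character(datasets$dataset))),
            ncol(proportions) == length(clusters))
  colnames(proportions) <- clusters
  if (any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("each dataset's cluster proportions must sum to 1")
  if (any(proportions < 0)) stop("negative cluster proportion")
  check_in <- function(x, universe, what)
    if (length(bad <- setdiff(x, universe)))
      stop("unknown ", what, ": ", paste(utils::head(bad, 5), collapse = ", "))
  check_in(planted_degs$gene, genes, "planted DEG gene")
  check_in(planted_degs$cluster, clusters, "planted DEG cluster")
  check_in(c(planted_lr$ligand, planted_lr$receptor, decoy_lr$ligand, decoy_lr$receptor),
           genes, "ligand/receptor gene")
  check_in(c(planted_lr$sender, planted_lr$receiver), clusters, "LR cluster")
  check_in(mito_genes, genes, "mitochondrial gene")
  if (!(nb_dispersion > 0)) stop("nb_dispersion must be > 0")
  stopifnot(length(libsize_lognormal) == 2, libsize_lognormal[2] >= 0)
  structure(list(
    genes = genes, clusters = clusters, profiles = profiles,
    datasets = datasets, proportions = proportions,
    planted_degs = planted_degs, planted_lr = planted_lr, decoy_lr = decoy_lr,
    mito_genes = mito_genes, nb_dispersion = nb_dispersion,
    libsize_lognormal = as.numeric(libsize_lognormal),
    lr_high = lr_high, seed = as.integer(seed)), class = "sim_config")
}

empty_deg_table <- function() data.frame(
  gene = character(), cluster = character(), condition = character(),
  lfc = numeric(), stringsAsFactors = FALSE)

empty_lr_table <- function() data.frame(
  ligand = character(), receptor = character(), sender = character(),
  receiver = character(), condition = character(), stringsAsFactors = FALSE)

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes, %d clusters, %d datasets; ",
                     "%d planted DEGs, %d planted LR pairs, %d decoy pairs (seed %d)\n"),
              length(x$genes), length(x$clusters), nrow(x$datasets),
              nrow(x$planted_degs), nrow(x$planted_lr), nrow(x$decoy_lr), x$seed))
  invisible(x)
}

#' Default simulation configuration
#'
#' Emulates the study design this package targets: seven datasets (uninjured
#' `UN`; `PBS1d/3d/7d` regenerative; `CL1d/3d/7d` macrophage-delayed), twelve
#' inflammatory clusters (`Mac1`-`Mac9`, `Neu1`, `Neu2`, `MN`), resident
#' macrophage clusters (`Mac2`, `Mac3`) enriched under PBS and collapsed under
#' CL, planted 4-fold condition-enriched genes, and planted condition-specific
#' ligand-receptor pairs among expressed-everywhere / silent decoy pairs.
#' Desk-scale defaults: 1000 genes x 2000 cells per dataset.
#'
#' @param seed base seed.
#' @param n_genes total gene universe size (including mitochondrial and
#'   ligand/receptor genes).
#' @param n_cells cells per dataset (recycled over the seven datasets).
#' @param n_planted_deg number of planted condition-enriched genes (split
#'   evenly between PBS and CL).
#' @param deg_lfc log2 fold change of planted genes (default 2, i.e. 4-fold).
#' @param n_planted_lr number of planted condition-specific ligand-receptor
#'   pairs (split evenly between PBS and CL).
#' @param n_decoy_lr number of decoy pairs (half expressed everywhere, half
#'   silent).
#' @param mito_frac expected mitochondrial fraction of UMIs per cell.
#' @param nb_dispersion negative binomial dispersion.
#' @param libsize_lognormal `(meanlog, sdlog)` of library-size factors.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, n_genes = 1000, n_cells = 2000,
                               n_planted_deg = 24, deg_lfc = 2,
                               n_planted_lr = 12, n_decoy_lr = 200,
                               mito_frac = 0.05, nb_dispersion = 0.1,
                               libsize_lognormal = c(0, 0.3)) {
  stopifnot(n_planted_lr %% 2 == 0, n_planted_deg %% 2 == 0)
  mito <- c("mt-nd1", "mt-nd2", "mt-nd3", "mt-nd4", "mt-nd5",
            "mt-co1", "mt-co2", "mt-co3", "mt-atp6", "mt-cyb")
  n_lr_genes <- 2 * n_planted_lr
  half <- n_planted_lr / 2
  lr_genes <- c(sprintf("ligP%02d", seq_len(half)), sprintf("recP%02d", seq_len(half)),
                sprintf("ligC%02d", seq_len(half)), sprintf("recC%02d", seq_len(half)))
  n_generic <- n_genes - length(mito) - n_lr_genes
  if (n_generic < 200) stop("n_genes too small for the default layout")
  generic <- sprintf("g%04d", seq_len(n_generic))
  genes <- c(generic, mito, lr_genes)

  clusters <- c(paste0("Mac", 1:9), "Neu1", "Neu2", "MN")
  datasets <- data.frame(
    dataset = c("UN", "PBS1d", "PBS3d", "PBS7d", "CL1d", "CL3d", "CL7d"),
    condition = c("UN", "PBS", "PBS", "PBS", "CL", "CL", "CL"),
    timepoint = c(0, 1, 3, 7, 1, 3, 7),
    n_cells = rep_len(n_cells, 7), stringsAsFactors = FALSE)

  # cluster mix: resident macrophages (Mac2, Mac3) dominate the uninjured
  # heart, persist under PBS and collapse under CL; neutrophils surge at 1d
  base_prop <- rbind(
    UN    = c(0.15, 0.25, 0.20, 0.08, 0.06, 0.05, 0.05, 0.04, 0.04, 0.03, 0.02, 0.03),
    PBS1d = c(0.10, 0.12, 0.09, 0.08, 0.07, 0.06, 0.06, 0.05, 0.05, 0.14, 0.10, 0.08),
    PBS3d = c(0.12, 0.15, 0.11, 0.09, 0.08, 0.07, 0.06, 0.05, 0.05, 0.09, 0.07, 0.06),
    PBS7d = c(0.13, 0.18, 0.13, 0.09, 0.08, 0.07, 0.06, 0.05, 0.05, 0.06, 0.05, 0.05),
    CL1d  = c(0.13, 0.02, 0.03, 0.10, 0.09, 0.08, 0.08, 0.07, 0.07, 0.15, 0.11, 0.07),
    CL3d  = c(0.15, 0.02, 0.03, 0.11, 0.10, 0.09, 0.08, 0.08, 0.07, 0.11, 0.09, 0.07),
    CL7d  = c(0.16, 0.03, 0.04, 0.11, 0.10, 0.09, 0.08, 0.08, 0.07, 0.09, 0.08, 0.07))
  proportions <- sweep(base_prop, 1, rowSums(base_prop), "/")

  with_seed(derive_seed(seed, 9999), {
    base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1.2)
    names(base) <- genes
    # mitochondrial genes sized so their expected UMI share is mito_frac
    base[lr_genes] <- 0.05
    mito_total <- mito_frac / (1 - mito_frac) * sum(base[setdiff(genes, mito)])
    base[mito] <- mito_total / length(mito)
    profiles <- matrix(base, nrow = length(genes), ncol = length(clusters),
                       dimnames = list(genes, clusters))
    # ~3% of generic genes per cluster up-weighted 6x as cluster markers
    n_mark <- max(5L, round(0.03 * n_generic))
    for (cl in clusters) {
      mk <- sample(generic, n_mark)
      profiles[mk, cl] <- profiles[mk, cl] * 6
    }

    # planted condition-enriched genes drawn from well-expressed generic genes
    detectable <- generic[base[generic] >= stats::median(base[generic])]
    deg_genes <- sample(detectable, n_planted_deg)
    planted_degs <- data.frame(
      gene = deg_genes,
      cluster = rep_len(clusters[1:8], n_planted_deg),
      condition = rep(c("PBS", "CL"), each = n_planted_deg / 2),
      lfc = deg_lfc, stringsAsFactors = FALSE)

    planted_lr <- data.frame(
      ligand = c(sprintf("ligP%02d", seq_len(half)), sprintf("ligC%02d", seq_len(half))),
      receptor = c(sprintf("recP%02d", seq_len(half)), sprintf("recC%02d", seq_len(half))),
      sender = rep_len(paste0("Mac", 1:6), n_planted_lr),
      receiver = rep_len(c("Neu1", "Neu2"), n_planted_lr),
      condition = rep(c("PBS", "CL"), each = half), stringsAsFactors = FALSE)

    # decoys: half from strongly expressed genes (shared in both conditions),
    # half from near-silent genes (absent in both); ambiguous mid-range genes
    # are avoided so decoy ground truth is unambiguous
    pool <- setdiff(generic, deg_genes)
    hi <- pool[base[pool] >= stats::quantile(base[pool], 0.90)]
    lo <- pool[base[pool] <= stats::quantile(base[pool], 0.10)]
    n_on <- floor(n_decoy_lr / 2); n_off <- n_decoy_lr - n_on
    decoy_lr <- unique(data.frame(
      ligand = c(sample(hi, n_on, replace = TRUE), sample(lo, n_off, replace = TRUE)),
      receptor = c(sample(hi, n_on, replace = TRUE), sample(lo, n_off, replace = TRUE)),
      stringsAsFactors = FALSE))
    decoy_lr <- decoy_lr[decoy_lr$ligand != decoy_lr$receptor, ]

    lr_high <- 8 * unname(stats::quantile(base[generic], 0.75))

    sim_config(genes = genes, clusters = clusters, profiles = profiles,
               datasets = datasets, proportions = proportions,
               planted_degs = planted_degs, planted_lr = planted_lr,
               decoy_lr = decoy_lr, mito_genes = mito,
               nb_dispersion = nb_dispersion,
               libsize_lognormal = libsize_lognormal,
               lr_high = lr_high, seed = seed)
  })
}

#' Generate one synthetic dataset
#'
#' Draws cluster sizes multinomially from the dataset's proportion vector,
#' assigns barcodes to clusters, and samples counts from a negative binomial
#' with cell-specific log-normal library-size factors. Planted
#' condition-enriched genes have their mean multiplied by `2^lfc` in their
#' cluster when the dataset's condition matches; planted ligand/receptor
#' genes are set to `lr_high` mean in their sender/receiver cluster under
#' their condition. Identical `(config, dataset)` yields bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @param dataset dataset identifier present in `config$datasets`.
#' @return List with `matrix` ([count_matrix()]), `annotation` (data.frame:
#'   `barcode`, `cluster`, `condition`, `timepoint`, `dataset`) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_dataset <- function(config, dataset) {
  stopifnot(inherits(config, "sim_config"))
  idx <- match(dataset, config$datasets$dataset)
  if (is.na(idx)) stop("unknown dataset id: ", dataset)
  ds <- config$datasets[idx, ]
  n <- ds$n_cells
  prop <- config$proportions[dataset, ]

  with_seed(derive_seed(config$seed, idx), {
    sizes <- as.vector(stats::rmultinom(1, n, prop))
    names(sizes) <- config$clusters
    cluster_vec <- sample(rep(config$clusters, sizes))
    sf <- stats::rlnorm(n, config$libsize_lognormal[1], config$libsize_lognormal[2])

    mu <- config$profiles[, cluster_vec, drop = FALSE]
    degs <- config$planted_degs
    degs <- degs[degs$condition == ds$condition, , drop = FALSE]
    for (i in seq_len(nrow(degs)))
      mu[degs$gene[i], cluster_vec == degs$cluster[i]] <-
        mu[degs$gene[i], cluster_vec == degs$cluster[i]] * 2^degs$lfc[i]
    lr <- config$planted_lr
    lr_active <- lr[lr$condition == ds$condition, , drop = FALSE]
    for (i in seq_len(nrow(lr_active))) {
      mu[lr_active$ligand[i], cluster_vec == lr_active$sender[i]] <- config$lr_high
      mu[lr_active$receptor[i], cluster_vec == lr_active$receiver[i]] <- config$lr_high
    }
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
      nrow = length(config$genes),
      dimnames = list(config$genes,
                      sprintf("%s_bc%05d", dataset, seq_len(n))))
    cm <- count_matrix(counts, dataset = dataset)

    annotation <- data.frame(
      barcode = colnames(counts), cluster = cluster_vec,
      condition = ds$condition, timepoint = ds$timepoint,
      dataset = dataset, stringsAsFactors = FALSE)

    deg_truth <- config$planted_degs
    if (nrow(deg_truth)) {
      deg_truth$active <- deg_truth$condition == ds$condition
      deg_truth$realized_mean <- vapply(seq_len(nrow(deg_truth)), function(i) {
        cells <- cluster_vec == deg_truth$cluster[i]
        if (any(cells)) mean(counts[deg_truth$gene[i], cells]) else NA_real_
      }, numeric(1))
    } else {
      deg_truth$active <- logical(0); deg_truth$realized_mean <- numeric(0)
    }
    lr_truth <- config$planted_lr
    lr_truth$active <- if (nrow(lr_truth)) lr_truth$condition == ds$condition else logical(0)

    truth <- structure(list(
      dataset = dataset,
      cluster_of = data.frame(barcode = colnames(counts), cluster = cluster_vec,
                              stringsAsFactors = FALSE),
      deg_table = deg_truth, lr_table = lr_truth,
      cluster_counts = data.frame(dataset = dataset, cluster = config$clusters,
                                  n_cells = as.integer(sizes),
                                  stringsAsFactors = FALSE)),
      class = "synthetic_truth")

    list(matrix = cm, annotation = annotation, truth = truth)
  })
}

#' Generate every dataset in a configuration
#'
#' @param config a [sim_config()].
#' @return Named list (by dataset id) of [generate_dataset()] results, plus
#'   attribute-free convenience element `annotation`: the row-bound
#'   annotation across datasets.
#' @export
generate_all_datasets <- function(config) {
  out <- lapply(config$datasets$dataset, function(d) generate_dataset(config, d))
  names(out) <- config$datasets$dataset
  out
}

#' Write / read synthetic ground truth
#'
#' Serializes a `synthetic_truth` object as four TSV files
#' (`cluster_assignments.tsv`, `deg_truth.tsv`, `lr_truth.tsv`,
#' `cluster_counts.tsv`) that round-trip exactly through [read_truth()].
#'
#' @param truth a `synthetic_truth` object.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$cluster_of, file.path(path, "cluster_assignments.tsv"))
  write_tsv(truth$deg_table, file.path(path, "deg_truth.tsv"))
  write_tsv(truth$lr_table, file.path(path, "lr_truth.tsv"))
  write_tsv(truth$cluster_counts, file.path(path, "cluster_counts.tsv"))
  writeLines(truth$dataset, file.path(path, "dataset.txt"))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  cls <- c(gene = "character", cluster = "character", condition = "character",
           ligand = "character", receptor = "character", sender = "character",
           receiver = "character", barcode = "character", dataset = "character")
  rd <- function(f) {
    df <- read_tsv(file.path(path, f))
    for (nm in intersect(names(df), names(cls))) df[[nm]] <- as.character(df[[nm]])
    df
  }
  structure(list(
    dataset = readLines(file.path(path, "dataset.txt"))[1],
    cluster_of = rd("cluster_assignments.tsv"),
    deg_table = rd("deg_truth.tsv"),
    lr_table = rd("lr_truth.tsv"),
    cluster_counts = rd("cluster_counts.tsv")), class = "synthetic_truth")
}
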