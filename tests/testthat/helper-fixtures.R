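# fixtures built in code; all randomness goes through withr::with_seed

random_count_matrix <- function(n_genes = 20, n_cells = 30, density = 0.3,
                                max_count = 50, dataset = "toy", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, n_genes, n_cells)
    nz <- sample(length(m), round(density * length(m)))
    m[nz] <- sample.int(max_count, length(nz), replace = TRUE)
    rownames(m) <- sprintf("g%03d", seq_len(n_genes))
    colnames(m) <- sprintf("bc%03d", seq_len(n_cells))
    count_matrix(m, dataset = dataset)
  })
}

random_annotation <- function(barcodes, clusters = c("A", "B", "C"),
                              dataset = "toy", condition = "PBS",
                              timepoint = 7, seed = 1) {
  withr::with_seed(seed, data.frame(
    barcode = barcodes,
    cluster = sample(clusters, length(barcodes), replace = TRUE),
    condition = condition, timepoint = timepoint, dataset = dataset,
    stringsAsFactors = FALSE))
}

# minimal two-cluster config for targeted generator checks
two_cluster_config <- function(p_a_by_dataset, n_cells = 2000, n_genes = 10,
                               seed = 1, planted_degs = NULL, lfc = 2) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  clusters <- c("A", "B")
  profiles <- matrix(2, n_genes, 2, dimnames = list(genes, clusters))
  datasets <- data.frame(
    dataset = names(p_a_by_dataset),
    condition = sub("[0-9]+d$", "", names(p_a_by_dataset)),
    timepoint = ifelse(grepl("[0-9]+d$", names(p_a_by_dataset)),
                       as.numeric(sub("^[A-Za-z]+", "", sub("d$", "", names(p_a_by_dataset)))), 0),
    n_cells = n_cells, stringsAsFactors = FALSE)
  prop <- cbind(A = unlist(p_a_by_dataset), B = 1 - unlist(p_a_by_dataset))
  degs <- if (is.null(planted_degs)) data.frame(
    gene = character(), cluster = character(), condition = character(),
    lfc = numeric(), stringsAsFactors = FALSE) else planted_degs
  sim_config(genes = genes, clusters = clusters, profiles = profiles,
             datasets = datasets, proportions = prop, planted_degs = degs,
             nb_dispersion = 0.1, seed = seed)
}

# dense brute-force pseudobulk oracle
dense_group_means <- function(cm, ann, groupby = c("cluster", "dataset")) {
  dense <- as.matrix(cm$counts)
  ann <- ann[match(colnames(dense), ann$barcode), ]
  key <- apply(ann[groupby], 1, paste, collapse = "|")
  out <- sapply(sort(unique(key)), function(k)
    rowMeans(dense[, key == k, drop = FALSE]))
  out
}
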