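#' Build a target-species ligand-receptor database by orthology
#'
#' Expands each human ligand-receptor pair through the ortholog map: every
#' pair maps to the Cartesian product of its ligand orthologs and receptor
#' orthologs (one-to-many orthology yields one row per combination, so
#' paralog receptors appear as distinct pairs). Pairs with an unmapped side
#' are dropped and counted. The result is deduplicated and sorted.
#'
#' @param human_pairs data.frame with columns `ligand` and `receptor`
#'   (human gene symbols); an optional `pair_id` column is carried through.
#' @param ortho data.frame ortholog map with columns `human_gene`,
#'   `target_gene` (one row per ortholog; one-to-many allowed).
#' @return List with `db` (data.frame: `ligand`, `receptor`, `human_ligand`,
#'   `human_receptor`) and `report` (`n_human_pairs`, `n_mapped`,
#'   `n_dropped_unmapped_ligand`, `n_dropped_unmapped_receptor`,
#'   `n_target_pairs`).
#' @export
build_lr_database <- function(human_pairs, ortho) {
  stopifnot(all(c("ligand", "receptor") %in% names(human_pairs)),
            all(c("human_gene", "target_gene") %in% names(ortho)),
            nrow(human_pairs) > 0)
  if (any(!nzchar(human_pairs$ligand)) || any(!nzchar(human_pairs$receptor)) ||
      anyNA(human_pairs$ligand) || anyNA(human_pairs$receptor))
    stop("malformed ligand-receptor pair rows")
  omap <- split(ortho$target_gene, ortho$human_gene)
  rows <- vector("list", nrow(human_pairs))
  miss_l <- 0L; miss_r <- 0L
  for (i in seq_len(nrow(human_pairs))) {
    lg <- omap[[human_pairs$ligand[i]]]
    rc <- omap[[human_pairs$receptor[i]]]
    if (is.null(lg) || !length(lg)) { miss_l <- miss_l + 1L; next }
    if (is.null(rc) || !length(rc)) { miss_r <- miss_r + 1L; next }
    rows[[i]] <- expand.grid(ligand = lg, receptor = rc,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[i]]$human_ligand <- human_pairs$ligand[i]
    rows[[i]]$human_receptor <- human_pairs$receptor[i]
  }
  db <- do.call(rbind, rows)
  if (is.null(db)) db <- data.frame(ligand = character(), receptor = character(),
                                    human_ligand = character(),
                                    human_receptor = character())
  db <- db[!duplicated(db[c("ligand", "receptor")]), , drop = FALSE]
  db <- db[order(db$ligand, db$receptor), , drop = FALSE]
  rownames(db) <- NULL
  list(db = db,
       report = data.frame(
         n_human_pairs = nrow(human_pairs),
         n_mapped = nrow(human_pairs) - miss_l - miss_r,
         n_dropped_unmapped_ligand = miss_l,
         n_dropped_unmapped_receptor = miss_r,
         n_target_pairs = nrow(db)))
}

#' Expressed gene set of a pseudobulk group
#'
#' A gene counts as expressed in a (cluster, dataset) group when its
#' normalized pseudobulk value reaches the group's upper-quantile cutoff:
#' the 75th percentile (linear interpolation) of the group's nonzero
#' normalized values by default. Ties at the cutoff are expressed (`>=`).
#'
#' @param pb a normalized `pseudobulk` object (see [normalize_pseudobulk()]).
#' @param cluster,dataset group coordinates.
#' @param quantile cutoff quantile (default 0.75).
#' @param nonzero_only compute the cutoff over nonzero values only (default
#'   TRUE); set FALSE to use all genes.
#' @return Character vector of expressed genes (empty, with a warning, for an
#'   all-zero group).
#' @export
expressed_genes <- function(pb, cluster, dataset, quantile = 0.75,
                            nonzero_only = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (is.null(pb$norm)) stop("pseudobulk table has no norm layer; run normalize_pseudobulk()")
  grp <- pb$groups$group[pb$groups$cluster == cluster & pb$groups$dataset == dataset]
  if (length(grp) != 1) stop("group not present: ", cluster, " / ", dataset)
  v <- pb$norm[, grp]
  vals <- if (nonzero_only) v[v > 0] else v
  if (!length(vals) || all(vals == 0)) {
    warning("group has no nonzero gene: ", grp)
    return(character())
  }
  cutoff <- unname(stats::quantile(vals, probs = quantile, type = 7))
  pb$genes[v >= cutoff & v > 0]
}

#' Enumerate ligand-receptor interaction edges
#'
#' Emits one edge per (sender, receiver, ligand-receptor pair) for which the
#' ligand is expressed in the sender cluster and the receptor in the
#' receiver cluster, within one dataset. Autocrine edges (sender ==
#' receiver) are allowed. Edges are ordered by (sender, receiver, ligand,
#' receptor).
#'
#' @param db ligand-receptor database data.frame (`ligand`, `receptor`).
#' @param expressed named list: cluster -> character vector of expressed
#'   genes in this dataset (e.g. from [expressed_genes()]).
#' @param senders,receivers cluster name vectors; each must have an entry in
#'   `expressed`.
#' @param dataset dataset label stamped on the edges.
#' @return data.frame: `sender`, `ligand`, `receptor`, `receiver`, `dataset`.
#' @export
enumerate_interactions <- function(db, expressed, senders, receivers, dataset) {
  stopifnot(all(c("ligand", "receptor") %in% names(db)))
  missing <- setdiff(c(senders, receivers), names(expressed))
  if (length(missing))
    stop("no expression call for cluster(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (s in senders) for (r in receivers) {
    hit <- db$ligand %in% expressed[[s]] & db$receptor %in% expressed[[r]]
    if (any(hit))
      rows[[length(rows) + 1]] <- data.frame(
        sender = s, ligand = db$ligand[hit], receptor = db$receptor[hit],
        receiver = r, dataset = dataset, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sender = character(), ligand = character(),
               receptor = character(), receiver = character(),
               dataset = character(), stringsAsFactors = FALSE)
  out <- out[order(out$sender, out$receiver, out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_key <- function(edges)
  paste(edges$sender, edges$receiver, edges$ligand, edges$receptor, sep = "\r")

#' Condition-specific interaction edges
#'
#' Compares two edge lists computed at a matched timepoint with the same
#' database, keyed by (sender, receiver, ligand, receptor) — the dataset
#' field is excluded from edge identity. Edges only in A are labeled
#' `"<label_a>-only"`, only in B `"<label_b>-only"`, and common edges
#' `"shared"`; the three sets partition the union exactly.
#'
#' @param edges_a,edges_b edge data.frames from [enumerate_interactions()].
#' @param label_a,label_b condition labels (default `"PBS"`, `"CL"`).
#' @param timepoint_a,timepoint_b optional timepoints; if both given they
#'   must match.
#' @return Edge data.frame (union of both lists, deduplicated on the edge
#'   key) with a `specificity` column.
#' @export
condition_specific_pairs <- function(edges_a, edges_b,
                                     label_a = "PBS", label_b = "CL",
                                     timepoint_a = NULL, timepoint_b = NULL) {
  if (!is.null(timepoint_a) && !is.null(timepoint_b) &&
      !identical(timepoint_a, timepoint_b))
    stop("mismatched timepoints: ", timepoint_a, " vs ", timepoint_b)
  ka <- unique(edge_key(edges_a)); kb <- unique(edge_key(edges_b))
  a <- edges_a[!duplicated(edge_key(edges_a)), , drop = FALSE]
  b <- edges_b[!duplicated(edge_key(edges_b)), , drop = FALSE]
  b_only <- b[!(edge_key(b) %in% ka), , drop = FALSE]
  out <- rbind(a[c("sender", "ligand", "receptor", "receiver")],
               b_only[c("sender", "ligand", "receptor", "receiver")])
  key <- edge_key(out)
  out$specificity <- ifelse(key %in% ka & key %in% kb, "shared",
                            ifelse(key %in% ka, paste0(label_a, "-only"),
                                   paste0(label_b, "-only")))
  out <- out[order(out$sender, out$receiver, out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize an interaction network
#'
#' Tallies interaction events per (sender, receiver) cluster pair and offers
#' Cytoscape-compatible exports.
#'
#' @param edges edge data.frame.
#' @return List with `counts` (sender x receiver integer matrix) and `edges`
#'   (the input).
#' @export
summarize_network <- function(edges) {
  senders <- sort(unique(edges$sender)); receivers <- sort(unique(edges$receiver))
  counts <- table(factor(edges$sender, levels = senders),
                  factor(edges$receiver, levels = receivers))
  counts <- matrix(as.integer(counts), nrow = length(senders),
                   dimnames = list(sender = senders, receiver = receivers))
  list(counts = counts, edges = edges)
}

#' Export edges in SIF format
#'
#' One row per edge: `sender<TAB>ligand:receptor<TAB>receiver` — the
#' Cytoscape simple-interaction format with the ligand-receptor pair as the
#' relationship type.
#'
#' @param edges edge data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  writeLines(paste(edges$sender, paste(edges$ligand, edges$receptor, sep = ":"),
                   edges$receiver, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(sender = character(), ligand = character(),
                      receptor = character(), receiver = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  lr <- do.call(rbind, strsplit(parts[, 2], ":", fixed = TRUE))
  data.frame(sender = parts[, 1], ligand = lr[, 1], receptor = lr[, 2],
             receiver = parts[, 3], stringsAsFactors = FALSE)
}

#' Export the cluster-level interaction-count graph as GraphML
#'
#' Builds a directed sender-to-receiver graph whose edge `weight` is the
#' number of ligand-receptor interaction events, and writes GraphML for
#' Cytoscape import.
#'
#' @param edges edge data.frame.
#' @param path output file.
#' @return The igraph object, invisibly.
#' @export
write_graphml <- function(edges, path) {
  net <- summarize_network(edges)
  idx <- which(net$counts > 0, arr.ind = TRUE)
  el <- data.frame(from = rownames(net$counts)[idx[, 1]],
                   to = colnames(net$counts)[idx[, 2]],
                   weight = net$counts[idx])
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = sort(unique(c(rownames(net$counts), colnames(net$counts)))))
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Read the demo human ligand-receptor table / ortholog map
#'
#' Small curated demonstration tables shipped with the package: a subset of
#' well-known human inflammatory ligand-receptor pairs and a human-to-
#' zebrafish ortholog map covering them (including one-to-many paralog
#' expansions). They illustrate the input format; they are not a full
#' database.
#'
#' @return data.frame in the format expected by [build_lr_database()].
#' @export
demo_human_lr_pairs <- function() {
  read_tsv(system.file("extdata", "lr_pairs_human_demo.tsv",
                       package = "cardiocomm", mustWork = TRUE))
}

#' @rdname demo_human_lr_pairs
#' @export
demo_ortholog_map <- function() {
  read_tsv(system.file("extdata", "ortholog_map_human_zebrafish_demo.tsv",
                       package = "cardiocomm", mustWork = TRUE))
}
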