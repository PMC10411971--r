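test_that("ortholog expansion is the Cartesian product with drop accounting", {
  pairs <- data.frame(ligand = c("L1", "L2", "L2", "L3"),
                      receptor = c("R1", "R2", "R2", "R3"))
  ortho <- data.frame(human_gene = c("L1", "R1", "R1", "L2", "R2"),
                      target_gene = c("l1", "r1a", "r1b", "l2", "r2"))
  res <- build_lr_database(pairs, ortho)
  # L1 -> {l1} x {r1a, r1b} = 2 pairs; duplicate L2-R2 collapses; L3 unmapped
  expect_equal(nrow(res$db), 3)
  expect_setequal(paste(res$db$ligand, res$db$receptor),
                  c("l1 r1a", "l1 r1b", "l2 r2"))
  expect_equal(res$report$n_dropped_unmapped_ligand, 1)
  expect_equal(res$report$n_target_pairs, 3)
  expect_error(build_lr_database(data.frame(ligand = "", receptor = "R"), ortho),
               "malformed")
})

test_that("the shipped demo tables expand cleanly", {
  res <- build_lr_database(demo_human_lr_pairs(), demo_ortholog_map())
  expect_gt(nrow(res$db), 30)            # one-to-many expansion
  expect_equal(res$report$n_dropped_unmapped_ligand, 1)    # UNMAPPEDLIG
  expect_equal(res$report$n_dropped_unmapped_receptor, 1)  # INSR absent
  expect_false(anyDuplicated(paste(res$db$ligand, res$db$receptor)) > 0)
})

mk_pb <- function(values, cluster = "A", dataset = "d") {
  m <- matrix(values, ncol = 1,
              dimnames = list(sprintf("g%02d", seq_along(values)), "b1"))
  # build via a one-cell group, then overwrite the norm layer directly
  ann <- data.frame(barcode = "b1", cluster = cluster, dataset = dataset)
  pb <- aggregate_pseudobulk(count_matrix(round(m) + 1), ann)
  pb$norm <- matrix(values, ncol = 1,
                    dimnames = list(pb$genes, pb$groups$group))
  pb$scale <- sum(values)
  pb
}

test_that("expressed genes are those at or above the nonzero upper quartile", {
  pb <- mk_pb(c(0, 1, 4, 10, 100))
  # nonzero {1,4,10,100}: cutoff 32.5 -> only the 100-valued gene
  expect_equal(expressed_genes(pb, "A", "d"), "g05")
  # ties at the cutoff are expressed
  pb2 <- mk_pb(rep(7, 4))
  expect_equal(expressed_genes(pb2, "A", "d"), sprintf("g%02d", 1:4))
  # all-zero group: empty set with a warning
  pb3 <- mk_pb(c(0, 0, 0))
  expect_warning(e <- expressed_genes(pb3, "A", "d"), "no nonzero")
  expect_length(e, 0)
  expect_error(expressed_genes(pb, "Z", "d"), "not present")
})

test_that("interaction enumeration matches the worked example and the oracle", {
  db <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  expr <- list(s = "L1", r = c("R1", "R2"))
  edges <- enumerate_interactions(db, expr, "s", "r", "d1")
  expect_equal(nrow(edges), 1)
  expect_equal(edges$ligand, "L1")
  expect_equal(edges$receptor, "R1")
  # empty expressed set on either side -> no edges
  expect_equal(nrow(enumerate_interactions(db, list(s = character(), r = "R1"),
                                           "s", "r", "d1")), 0)
  # autocrine edges allowed
  expr2 <- list(s = c("L1", "R1"))
  auto <- enumerate_interactions(db, expr2, "s", "s", "d1")
  expect_equal(nrow(auto), 1)
  expect_error(enumerate_interactions(db, expr, "s", "missing", "d1"),
               "no expression call")

  # triple-loop brute force on random instances
  for (seed in 1:5) {
    withr::with_seed(seed, {
      genes <- sprintf("G%02d", 1:30)
      db_r <- unique(data.frame(ligand = sample(genes, 40, TRUE),
                                receptor = sample(genes, 40, TRUE)))
      cl <- c("c1", "c2", "c3")
      expr_r <- lapply(cl, function(x) sample(genes, sample(5:15, 1)))
      names(expr_r) <- cl
      got <- enumerate_interactions(db_r, expr_r, cl, cl, "d")
      brute <- list()
      for (s in cl) for (r in cl) for (i in seq_len(nrow(db_r)))
        if (db_r$ligand[i] %in% expr_r[[s]] && db_r$receptor[i] %in% expr_r[[r]])
          brute[[length(brute) + 1]] <- paste(s, db_r$ligand[i],
                                              db_r$receptor[i], r)
      expect_setequal(paste(got$sender, got$ligand, got$receptor, got$receiver),
                      unlist(brute))
    })
  }
})

test_that("edge counts grow monotonically with the expressed sets", {
  withr::with_seed(2, {
    genes <- sprintf("G%02d", 1:20)
    db <- unique(data.frame(ligand = sample(genes, 30, TRUE),
                            receptor = sample(genes, 30, TRUE)))
    small <- list(a = genes[1:5], b = genes[1:5])
    large <- list(a = genes[1:12], b = genes[1:12])
    n_small <- nrow(enumerate_interactions(db, small, "a", "b", "d"))
    n_large <- nrow(enumerate_interactions(db, large, "a", "b", "d"))
    expect_gte(n_large, n_small)
    n_half_db <- nrow(enumerate_interactions(db[1:10, ], large, "a", "b", "d"))
    expect_gte(n_large, n_half_db)
  })
})

test_that("condition-specific labels form an exact partition", {
  mk <- function(keys, dataset) data.frame(
    sender = "s", ligand = keys, receptor = paste0(keys, "r"),
    receiver = "r", dataset = dataset, stringsAsFactors = FALSE)
  a <- mk(c("a", "b", "c"), "PBS7d"); b <- mk(c("b", "d"), "CL7d")
  lab <- condition_specific_pairs(a, b)
  expect_setequal(lab$ligand[lab$specificity == "PBS-only"], c("a", "c"))
  expect_equal(lab$ligand[lab$specificity == "CL-only"], "d")
  expect_equal(lab$ligand[lab$specificity == "shared"], "b")
  expect_equal(nrow(lab), 4)  # partition of the union, no duplicates
  # A = B -> all shared; disjoint -> none shared
  expect_true(all(condition_specific_pairs(a, a)$specificity == "shared"))
  expect_false(any(condition_specific_pairs(mk("x", "p"), mk("y", "c"))$specificity
                   == "shared"))
  expect_error(condition_specific_pairs(a, b, timepoint_a = 7, timepoint_b = 3),
               "mismatched timepoints")
})

test_that("network summaries and exports preserve the edge multiset", {
  withr::with_seed(5, {
    edges <- data.frame(
      sender = sample(c("m1", "m2"), 20, TRUE),
      ligand = sample(sprintf("L%d", 1:4), 20, TRUE),
      receptor = sample(sprintf("R%d", 1:4), 20, TRUE),
      receiver = sample(c("n1", "n2"), 20, TRUE),
      dataset = "d", stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges), ]
    net <- summarize_network(edges)
    for (s in rownames(net$counts)) for (r in colnames(net$counts))
      expect_equal(net$counts[s, r],
                   sum(edges$sender == s & edges$receiver == r))
    # single edge -> single 1
    one <- summarize_network(edges[1, ])
    expect_equal(as.vector(one$counts), 1L)
    # SIF round-trip preserves the edge multiset
    sif <- withr::local_tempfile(fileext = ".sif")
    write_sif(edges, sif)
    back <- read_sif(sif)
    expect_setequal(paste(back$sender, back$ligand, back$receptor, back$receiver),
                    paste(edges$sender, edges$ligand, edges$receptor, edges$receiver))
    # GraphML is readable and carries the counts as weights
    gml <- withr::local_tempfile(fileext = ".graphml")
    write_graphml(edges, gml)
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(sum(igraph::E(g)$weight), nrow(edges))
  })
})
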