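test_that("aggregation reproduces group means and sums exactly", {
  m <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), c("b1", "b2", "b3")))
  m["g1", ] <- c(3, 5, 10)
  ann <- data.frame(barcode = c("b1", "b2", "b3"),
                    cluster = c("A", "A", "B"), dataset = "d1")
  pb <- aggregate_pseudobulk(count_matrix(m), ann)
  grpA <- pb$groups$group[pb$groups$cluster == "A"]
  expect_equal(pb$raw_mean["g1", grpA], 4)   # cells {3, 5}
  expect_equal(pb$raw_sum["g1", grpA], 8)
  expect_equal(pb$raw_mean["g2", ], c(0, 0), ignore_attr = TRUE)
  # single-cell group equals the cell itself
  grpB <- pb$groups$group[pb$groups$cluster == "B"]
  expect_equal(pb$raw_mean["g1", grpB], 10)
  # identity raw_mean * n_cells == raw_sum
  expect_equal(sweep(pb$raw_mean, 2, pb$groups$n_cells, "*"), pb$raw_sum)
})

test_that("aggregation equals the dense brute-force oracle on random input", {
  for (seed in 1:3) {
    cm <- random_count_matrix(n_genes = 25, n_cells = 40, seed = seed)
    ann <- random_annotation(cm$barcodes, seed = seed + 10)
    pb <- aggregate_pseudobulk(cm, ann)
    oracle <- dense_group_means(cm, ann)
    expect_equal(pb$raw_mean[, colnames(oracle)], oracle)
  }
})

test_that("annotation mismatches are detected", {
  cm <- random_count_matrix(seed = 2)
  ann <- random_annotation(cm$barcodes, seed = 2)
  expect_error(aggregate_pseudobulk(cm, rbind(ann, data.frame(
    barcode = "ghost", cluster = "A", condition = "PBS",
    timepoint = 7, dataset = "toy"))), "absent from matrix")
  expect_error(aggregate_pseudobulk(cm, ann[-1, ]), "lack annotation")
})

test_that("normalization is column-stochastic up to scale", {
  m <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("b1", "b2")))
  m["g1", "b1"] <- 8; m["g2", "b1"] <- 2; m["g1", "b2"] <- 5
  ann <- data.frame(barcode = c("b1", "b2"), cluster = c("A", "B"),
                    dataset = "d1")
  pb <- normalize_pseudobulk(aggregate_pseudobulk(count_matrix(m), ann))
  grpA <- pb$groups$group[pb$groups$cluster == "A"]
  expect_equal(pb$norm["g1", grpA], 8e5)
  expect_equal(pb$norm["g2", grpA], 2e5)
  expect_equal(unname(colSums(pb$norm)), rep(1e6, 2))
  # single nonzero gene takes the whole scale
  grpB <- pb$groups$group[pb$groups$cluster == "B"]
  expect_equal(pb$norm["g1", grpB], 1e6)

  cm2 <- random_count_matrix(n_genes = 30, n_cells = 50, density = 0.5, seed = 4)
  ann2 <- random_annotation(cm2$barcodes, seed = 4)
  pb2 <- normalize_pseudobulk(aggregate_pseudobulk(cm2, ann2), scale = 1e4)
  expect_equal(unname(colSums(pb2$norm)), rep(1e4, nrow(pb2$groups)))
})

test_that("a zero-total group fails normalization by name", {
  m <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("b1", "b2")))
  m["g1", "b1"] <- 3
  ann <- data.frame(barcode = c("b1", "b2"), cluster = c("A", "B"), dataset = "d1")
  pb <- aggregate_pseudobulk(count_matrix(m), ann)
  expect_error(normalize_pseudobulk(pb), "B")
})

test_that("upper-quartile factors follow the quantile arithmetic", {
  # linear-interpolation quantile of {1,4,10,100}: 10 + 0.25 * 90 = 32.5
  expect_equal(unname(stats::quantile(c(1, 4, 10, 100), 0.75, type = 7)), 32.5)
  x <- cbind(s1 = c(1, 4, 10, 100), s2 = c(1, 4, 10, 100))
  expect_equal(unname(upper_quartile_factors(x)), c(1, 1))
  # UQs (20, 80) -> factors (0.5, 2) around geometric mean 40
  y <- cbind(s1 = rep(20, 5), s2 = rep(80, 5))
  expect_equal(unname(upper_quartile_factors(y)), c(0.5, 2))
  # zeros are excluded from the quantile
  z <- cbind(s1 = c(0, 0, 0, 1, 4, 10, 100))
  expect_equal(unname(upper_quartile_factors(z)), 1)
  expect_error(upper_quartile_factors(cbind(a = c(0, 0))), "all-zero")
})

test_that("average expression reference groups by cluster and timepoint", {
  cm <- random_count_matrix(n_genes = 10, n_cells = 20, seed = 6)
  ann <- random_annotation(cm$barcodes, clusters = c("A", "B"), seed = 6)
  ann$timepoint <- rep(c(1, 3), each = 10)
  ref <- average_expression_reference(cm, ann)
  expect_setequal(ref$groupby, c("cluster", "timepoint"))
  oracle <- dense_group_means(cm, ann, groupby = c("cluster", "timepoint"))
  expect_equal(ref$raw_mean[, colnames(oracle)], oracle)
})

test_that("marker detection filter and rank-sum retention behave as specified", {
  withr::with_seed(42, {
    n_in <- 200; n_out <- 800
    m <- matrix(rpois(3 * (n_in + n_out), 2), nrow = 3,
                dimnames = list(c("marker", "flat", "rare"),
                                sprintf("b%04d", seq_len(n_in + n_out))))
    in_cl <- seq_len(n_in)
    m["marker", in_cl] <- rpois(n_in, 16)           # planted 8-fold marker
    m["rare", ] <- 0
    m["rare", sample(in_cl, 0.2 * n_in)] <- 5       # detected in 20% only
    ann <- data.frame(barcode = colnames(m),
                      cluster = c(rep("X", n_in), rep("rest", n_out)))
    res <- marker_genes(count_matrix(m), ann, "X")
    expect_false("rare" %in% res$gene)              # fails >= 25% detection
    expect_true(res$marker[res$gene == "marker"])
    expect_gt(res$avg_log2FC[res$gene == "marker"], 0)
    expect_false(isTRUE(res$marker[res$gene == "flat"]))
    # invariant to barcode and gene order
    perm <- sample(ncol(m))
    res2 <- marker_genes(count_matrix(m[c(2, 1, 3), perm]),
                         ann[perm, ], "X")
    expect_equal(res2, res)
  })
})
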