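test_that("the M-D statistic follows its definition", {
  expect_equal(compute_md(8, 2), data.frame(M = 2, D = 6))
  expect_equal(compute_md(7, 7), data.frame(M = 0, D = 0))
  # zero replacement: (4, 0) with k = 0.5 -> M = log2(8) = 3, D = 3.5
  expect_equal(compute_md(4, 0, k = 0.5), data.frame(M = 3, D = 3.5))
  expect_error(compute_md(-1, 2), "negative")
  # vectorized
  md <- compute_md(c(8, 7, 4), c(2, 7, 0))
  expect_equal(md$M, c(2, 0, 3))
  expect_equal(md$D, c(6, 0, 3.5))
})

test_that("technical replicates have the prescribed library size", {
  x <- c(a = 10, b = 0, c = 90)
  reps <- simulate_technical_replicates(x, pnr = 0.2, nss = 5, seed = 1)
  expect_equal(dim(reps), c(3L, 5L))
  expect_equal(unname(colSums(reps)), rep(20, 5))
  # pnr = 1, nv = 0, single expressed category reproduces the sample exactly
  y <- c(0, 0, 50)
  reps2 <- simulate_technical_replicates(y, pnr = 1, nss = 3, nv = 0, seed = 1)
  expect_equal(unname(reps2), matrix(c(0, 0, 50), 3, 3))
  # reproducible under a fixed seed
  expect_identical(simulate_technical_replicates(x, seed = 9),
                   simulate_technical_replicates(x, seed = 9))
})

test_that("null size is genes x within-condition pairs", {
  g100 <- matrix(stats::rpois(200, 20), nrow = 100)
  null1 <- build_null(list(c1 = g100))               # C(2,2) = 1 pair
  expect_equal(nrow(null1), 100)
  g10a <- matrix(stats::rpois(30, 20), nrow = 10)
  g10b <- matrix(stats::rpois(30, 20), nrow = 10)
  null2 <- build_null(list(c1 = g10a, c2 = g10b))    # 3 + 3 pairs x 10 genes
  expect_equal(nrow(null2), 60)
  # identical replicates give a degenerate null at the origin
  same <- matrix(rep(c(5, 3, 0), 2), nrow = 3)
  null3 <- build_null(list(c1 = same))
  expect_equal(null3$m, rep(0, 3))
  expect_equal(null3$d, rep(0, 3))
  expect_error(build_null(list(c1 = matrix(1, 3, 1))), "no within-condition")
})

test_that("differential probability counts dominated null points", {
  null <- structure(data.frame(m = 0:3, d = 0:3),
                    class = c("md_null", "data.frame"))
  expect_equal(differential_probability(2.5, 2.5, null), 0.75)
  expect_equal(differential_probability(10, 10, null), 1)
  expect_equal(differential_probability(0, 0, null), 0.25)  # ties to the null
  expect_equal(differential_probability(-2.5, 2.5, null), 0.75)  # |M|
})

test_that("differential probability equals the brute-force double loop", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      null <- structure(
        data.frame(m = abs(stats::rnorm(200)), d = abs(stats::rnorm(200, sd = 5))),
        class = c("md_null", "data.frame"))
      M <- stats::rnorm(50); D <- abs(stats::rnorm(50, sd = 5))
      q <- differential_probability(M, D, null)
      brute <- sapply(seq_along(M), function(g) {
        hits <- 0
        for (i in seq_len(nrow(null)))
          if (null$m[i] <= abs(M[g]) && null$d[i] <= D[g]) hits <- hits + 1
        hits / nrow(null)
      })
      expect_identical(q, brute)
      # invariant to permutation of the null
      perm <- sample(nrow(null))
      expect_equal(differential_probability(M, D, null[perm, ]), q)
    })
  }
})

test_that("q is jointly monotone in |M| and D", {
  withr::with_seed(3, {
    null <- structure(
      data.frame(m = abs(stats::rnorm(300)), d = abs(stats::rnorm(300, sd = 2))),
      class = c("md_null", "data.frame"))
    m_grid <- seq(0, 3, length.out = 7)
    d_grid <- seq(0, 6, length.out = 7)
    qs <- outer(m_grid, d_grid, function(m, d) differential_probability(m, d, null))
    expect_true(all(diff(qs) >= 0))        # increasing in |M| per column
    expect_true(all(t(diff(t(qs))) >= 0))  # increasing in D per row
  })
})

test_that("swapping samples flips M and preserves D and q", {
  withr::with_seed(8, {
    x1 <- stats::rnbinom(300, mu = 100, size = 20)
    x2 <- stats::rnbinom(300, mu = 100, size = 20)
    names(x1) <- names(x2) <- sprintf("g%03d", 1:300)
    a <- call_degs(x1, x2, seed = 5)
    b <- call_degs(x2, x1, seed = 5)
    a <- a[order(a$gene), ]; b <- b[order(b$gene), ]
    expect_equal(b$M, -a$M)
    expect_equal(b$D, a$D)
    expect_equal(b$q, a$q)
  })
})

test_that("call_degs applies a strict threshold and sorts deterministically", {
  withr::with_seed(2, {
    x1 <- stats::rnbinom(200, mu = 200, size = 50)
    x2 <- stats::rnbinom(200, mu = 200, size = 50)
    names(x1) <- names(x2) <- sprintf("g%03d", 1:200)
    res <- call_degs(x1, x2, q_threshold = 1, seed = 3)
    expect_equal(sum(res$call), 0)         # q <= 1 always
    expect_true(all(diff(res$q) <= 0))
    expect_identical(res, call_degs(x1, x2, q_threshold = 1, seed = 3))
  })
})

test_that("pseudobulk contrasts recover a planted cluster-restricted change", {
  degs <- data.frame(gene = c("g03", "g07"), cluster = c("A", "A"),
                     condition = c("PBS", "CL"), lfc = 2)
  cfg <- two_cluster_config(list(PBS7d = 0.5, CL7d = 0.5), n_cells = 1200,
                            n_genes = 40, seed = 13, planted_degs = degs)
  runs <- generate_all_datasets(cfg)
  ann <- rbind(runs$PBS7d$annotation, runs$CL7d$annotation)
  pb <- aggregate_pseudobulk(list(runs$PBS7d$matrix, runs$CL7d$matrix), ann)
  de <- pseudobulk_de(pb, "PBS7d", "CL7d", q_threshold = 0.8, seed = 21)
  a <- de$A
  expect_true(a$call[a$gene == "g03"] && a$M[a$gene == "g03"] > 0)
  expect_true(a$call[a$gene == "g07"] && a$M[a$gene == "g07"] < 0)
  # cluster B saw no planted change in these genes
  b <- de$B
  expect_false(any(b$call[b$gene %in% c("g03", "g07")]))
})
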