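#' The M-D statistic
#'
#' For paired non-negative expression values, zeros are replaced by `k` and
#' the pair summarized as `M = log2(x1/x2)` (log2 expression ratio) and
#' `D = |x1 - x2|` (absolute difference, in the units of the input).
#' Vectorized over genes.
#'
#' @param x1,x2 non-negative numeric vectors (normalized expression).
#' @param k zero-replacement constant (default 0.5), applied only to zeros.
#' @return data.frame with columns `M` and `D`.
#' @export
compute_md <- function(x1, x2, k = 0.5) {
  if (any(x1 < 0) || any(x2 < 0)) stop("negative expression values")
  stopifnot(length(x1) == length(x2), k > 0)
  x1 <- ifelse(x1 == 0, k, x1)
  x2 <- ifelse(x2 == 0, k, x2)
  data.frame(M = log2(x1 / x2), D = abs(x1 - x2))
}

#' Simulate technical replicates of a count sample
#'
#' Draws `nss` replicate count vectors from a multinomial of size
#' `round(pnr * sum(sample))`, with category probabilities proportional to
#' the observed counts perturbed by multiplicative uniform noise on
#' `[1 - nv, 1 + nv]`. This supplies a within-condition noise distribution
#' for designs without real replicates.
#'
#' @param sample non-negative integer count vector (sums to > 0).
#' @param pnr fraction of the library size drawn per replicate (0 < pnr <= 1).
#' @param nss number of replicates (>= 2).
#' @param nv relative probability perturbation per replicate.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return Matrix genes x `nss` of replicate counts; every column sums to
#'   `round(pnr * sum(sample))`.
#' @export
simulate_technical_replicates <- function(sample, pnr = 0.2, nss = 5,
                                          nv = 0.02, seed = NULL) {
  stopifnot(all(sample >= 0), sum(sample) > 0, pnr > 0, pnr <= 1, nss >= 2, nv >= 0)
  draw <- function() {
    size <- round(pnr * sum(sample))
    reps <- vapply(seq_len(nss), function(r) {
      p <- sample * stats::runif(length(sample), 1 - nv, 1 + nv)
      as.vector(stats::rmultinom(1, size, p))
    }, numeric(length(sample)))
    rownames(reps) <- names(sample)
    reps
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Pool a within-condition noise distribution
#'
#' Computes the (|M|, D) statistic for every within-condition pair of
#' replicate columns and every gene, pooled over conditions. With `r_c`
#' replicates in condition `c`, the null holds
#' `n_genes * sum_c choose(r_c, 2)` points.
#'
#' @param replicates named list (by condition) of genes x replicates numeric
#'   matrices on the same expression scale as the signal.
#' @param k zero-replacement constant; must match the signal's.
#' @return An object of class `md_null`: data.frame with columns `m` (= |M|)
#'   and `d`.
#' @export
build_null <- function(replicates, k = 0.5) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  pts <- list()
  for (cond in names(replicates)) {
    mat <- as.matrix(replicates[[cond]])
    r <- ncol(mat)
    if (r < 2) next
    for (i in seq_len(r - 1)) for (j in seq(i + 1, r)) {
      md <- compute_md(mat[, i], mat[, j], k = k)
      pts[[length(pts) + 1]] <- data.frame(m = abs(md$M), d = md$D)
    }
  }
  if (!length(pts)) stop("no within-condition replicate pair available")
  structure(do.call(rbind, c(pts, list(make.row.names = FALSE))),
            class = c("md_null", "data.frame"))
}

#' Differential probability of an (M, D) point against a noise null
#'
#' `q` is the fraction of null points dominated by the signal:
#' `q = #{(m, d) in null : m <= |M| and d <= D} / |null|`. Comparisons are
#' non-strict, so ties count toward the null (conservative). Vectorized over
#' signal points.
#'
#' @param M,D numeric vectors (signal log2 ratios and absolute differences).
#' @param null an `md_null` from [build_null()] (non-empty).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
differential_probability <- function(M, D, null) {
  stopifnot(length(M) == length(D), nrow(null) >= 1)
  nm <- null$m; nd <- null$d; am <- abs(M)
  vapply(seq_along(am),
         function(i) mean(nm <= am[i] & nd <= D[i]),
         numeric(1))
}

#' Call differentially expressed genes from two count samples
#'
#' Full M-D pipeline for a two-sample (replicate-free) design: both samples
#' are scaled to counts-per-`scale`; the signal (M, D) is computed per gene;
#' technical replicates are simulated from each sample's raw counts, scaled
#' likewise, and pooled into the noise null; each gene's differential
#' probability `q` is its dominance fraction over the null. A gene is called
#' when `q > q_threshold` (strict).
#'
#' @param x1,x2 named non-negative count vectors over the same gene universe
#'   (condition 1 and condition 2).
#' @param k zero-replacement constant (default 0.5).
#' @param pnr,nss,nv replicate-simulation parameters, see
#'   [simulate_technical_replicates()].
#' @param q_threshold probability threshold for a call (default 0.99).
#' @param scale library-size scaling constant (default `1e6`, i.e. CPM).
#' @param seed seed for replicate simulation.
#' @return data.frame of class `deg_table`: `gene`, `M`, `D`, `q`, `call`,
#'   sorted by `q` desc, `|M|` desc, then gene id. The null is attached as
#'   attribute `"null"`.
#' @export
call_degs <- function(x1, x2, k = 0.5, pnr = 0.2, nss = 5, nv = 0.02,
                      q_threshold = 0.99, scale = 1e6, seed = 1L) {
  stopifnot(length(x1) == length(x2))
  genes <- names(x1)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_along(x1))
  if (!is.null(names(x2)) && !identical(genes, names(x2)))
    stop("x1 and x2 must share the same gene universe and order")
  if (sum(x1) <= 0 || sum(x2) <= 0) stop("each sample must have positive total counts")

  cps <- function(v) v / sum(v) * scale
  signal <- compute_md(cps(x1), cps(x2), k = k)
  # same derived seed for both samples, so swapping x1/x2 leaves the pooled
  # null (and hence q) unchanged
  reps1 <- simulate_technical_replicates(x1, pnr, nss, nv, seed = derive_seed(seed, 1))
  reps2 <- simulate_technical_replicates(x2, pnr, nss, nv, seed = derive_seed(seed, 1))
  null <- build_null(list(cond1 = apply(reps1, 2, cps),
                          cond2 = apply(reps2, 2, cps)), k = k)
  q <- differential_probability(signal$M, signal$D, null)
  res <- data.frame(gene = genes, M = signal$M, D = signal$D, q = q,
                    call = q > q_threshold, stringsAsFactors = FALSE)
  res <- res[order(-res$q, -abs(res$M), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "null") <- null
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Condition-enriched genes per cluster from a pseudobulk table
#'
#' Runs [call_degs()] on each cluster's summed pseudobulk counts between two
#' datasets (or pooled dataset sets) of opposite conditions.
#'
#' @param pb a `pseudobulk` object grouped by `(cluster, dataset)`.
#' @param datasets_a,datasets_b dataset ids pooled (summed) per side.
#' @param clusters clusters to test; default all clusters present on both
#'   sides.
#' @param q_threshold probability threshold (default 0.8 for pseudobulk
#'   contrasts; 0.99 is the bulk convention).
#' @param ... further arguments to [call_degs()].
#' @param seed base seed; one derived seed per cluster.
#' @return Named list of `deg_table` data.frames, one per cluster.
#' @export
pseudobulk_de <- function(pb, datasets_a, datasets_b, clusters = NULL,
                          q_threshold = 0.8, seed = 1L, ...) {
  stopifnot(inherits(pb, "pseudobulk"), "dataset" %in% pb$groupby)
  g <- pb$groups
  pool <- function(cl, dss) {
    cols <- g$group[g$cluster == cl & g$dataset %in% dss]
    if (!length(cols)) return(NULL)
    rowSums(pb$raw_sum[, cols, drop = FALSE])
  }
  if (is.null(clusters)) {
    clusters <- sort(unique(g$cluster[g$dataset %in% c(datasets_a, datasets_b)]))
    clusters <- clusters[vapply(clusters, function(cl)
      !is.null(pool(cl, datasets_a)) && !is.null(pool(cl, datasets_b)), logical(1))]
  }
  out <- lapply(seq_along(clusters), function(i) {
    a <- pool(clusters[i], datasets_a); b <- pool(clusters[i], datasets_b)
    if (is.null(a) || is.null(b))
      stop("cluster absent on one side of the contrast: ", clusters[i])
    call_degs(a, b, q_threshold = q_threshold, seed = derive_seed(seed, i), ...)
  })
  names(out) <- clusters
  out
}
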