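# internal helpers shared across modules

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stage/dataset seed from a base seed; kept inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + offset * 131) %% 2147483647L
}

# deterministic TSV writer used for all tabular outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# upper-quartile (75th percentile, linear interpolation) of the nonzero values
uq_nonzero <- function(x, probs = 0.75) {
  nz <- x[x > 0]
  if (!length(nz)) return(NA_real_)
  unname(stats::quantile(nz, probs = probs, type = 7))
}
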