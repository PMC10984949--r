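# small shared helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from (seed, stream label); keeps results < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# scatter-add: sum rows of `values` grouped by `index` into an n_out x d matrix
scatter_sum <- function(values, index, n_out) {
  out <- matrix(0, n_out, ncol(values))
  if (length(index) > 0L) {
    rs <- rowsum(values, group = index)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

col_vars_biased <- function(x) {
  mu <- colMeans(x)
  colMeans(x^2) - mu^2
}
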