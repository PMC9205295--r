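`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. seed = NULL uses (and advances) the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, kept within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483647)
}
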