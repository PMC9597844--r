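#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so seeded helpers do not disturb the
#' global random stream. A `NULL` seed evaluates `expr` with the current
#' stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-replicate seed derived from (seed, r); kept < 2^31 so it
# is always a valid R integer seed.
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + as.numeric(r) * 104729) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
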