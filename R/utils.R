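#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so seeded helpers never perturb the
#' surrounding random stream.
#'
#' @param seed Integer seed, or `NULL` to run unseeded.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme so that pipeline stages (and per-pair null
#' models) can be re-run in isolation. Stays within 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param i Non-negative counter.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1000003L + 1) * 1009 + i * 7919) %% 2147483629L
}

# Fast row-wise minima of a numeric matrix (max.col runs in C).
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
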