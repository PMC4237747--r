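# Internal helpers shared across modules.

#' Mid-rank percentile of each value within its own vector
#'
#' The empirical percentile used throughout the package for MAF-binned tau
#' ranks, F_ST class ranks and lnRsb region ranks: for value v_i,
#' (number strictly below + half the ties, self included) / n. A strict
#' maximum among n distinct values gets (n - 0.5)/n; a fully tied vector
#' gets 0.5 everywhere.
#'
#' @param x numeric vector (NAs not allowed).
#' @return numeric vector of percentiles in (0, 1).
#' @keywords internal
mid_rank <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL runs code untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the length-1 surprise: sample_vec(5L, 1) draws from c(5L).
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
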