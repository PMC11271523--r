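#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All stochastic
#' entry points in the package route through this so that a user's session
#' RNG stream is never silently consumed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps values in 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629L)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Permutation-model-adjusted agreement between two partitions of the same
#' cells; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}
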