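#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so library code never leaks
#' RNG side effects into the caller's session. With `seed = NULL` the
#' expression simply runs against the current RNG stream (this is how all
#' cohort-level randomness is funnelled through a single config seed).
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# sample SD of a numeric vector, NA-safe where stated by callers
sample_sd <- function(x) stats::sd(x)

#' Z-score a series (sample SD)
#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_invalid("cannot z-score a constant series")
  (x - mean(x)) / s
}

# block-average x (length n*k) down to length n
block_average <- function(x, k) {
  k <- as.integer(k)
  stopifnot(k >= 1, length(x) %% k == 0)
  if (k == 1L) return(x)
  colMeans(matrix(x, nrow = k))
}
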