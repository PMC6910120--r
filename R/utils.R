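# Internal helpers: argument checking, seed management.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  as.numeric(x)
}

assert_count <- function(x, name, lower = 1L) {
  x <- assert_number(x, name, lower = lower)
  if (x != round(x)) stopf("`%s` must be an integer, got %s", name, x)
  as.integer(x)
}

assert_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be a single number strictly between 0 and 1")
  as.numeric(alpha)
}

assert_matrix <- function(x, name) {
  if (inherits(x, "continuum_sample")) x <- unclass(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix (rows = observations, columns = nodes)", name)
  if (!all(is.finite(x)))
    stopf("`%s` contains non-finite values", name)
  x
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so seeded generation does not disturb the caller's stream.
#' A `NULL` seed evaluates `expr` with the RNG as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- assert_count(seed, "seed", lower = 0L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed from a root seed and integer components.
# Double-precision arithmetic is exact here: 69069 * (2^31 - 1) < 2^53.
derive_seed <- function(root, ...) {
  comps <- c(root, ...)
  if (any(!is.finite(comps))) stopf("seed components must be finite")
  h <- 0
  for (cmp in comps) {
    h <- (h * 69069 + (abs(round(cmp)) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}
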