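#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed by a fixed per-component offset.
# Offsets are fixed so adding a component never perturbs existing streams.
# Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset) %% 2147483647)
}

#' Approximate a non-negative numeric as a small rational
#'
#' Used to put DTL event costs on an exact integer scale so that "minimum
#' cost" is well defined without floating-point comparisons.
#'
#' @param x Non-negative numeric scalar.
#' @param max_den Largest denominator tried.
#' @return Integer vector `c(numerator, denominator)`.
#' @keywords internal
as_rational <- function(x, max_den = 1e6) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x >= 0)
  for (den in c(1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 100, 1000, 1e4, 1e6)) {
    if (den > max_den) break
    num <- round(x * den)
    if (abs(num / den - x) < 1e-9) return(c(num, den))
  }
  stop("cost ", x, " is not representable as a small rational", call. = FALSE)
}

lcm2 <- function(a, b) a / gcd2(a, b) * b
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

`%||%` <- function(a, b) if (is.null(a)) b else a
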