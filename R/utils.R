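#' @import methods
#' @importFrom stats cor sd rnorm runif oneway.test ptukey p.adjust t.test
#'   setNames dist
#' @importFrom utils write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global random-number state set from \code{seed},
#' restoring the previous state afterwards so package functions never clobber
#' the caller's RNG stream. A \code{NULL} seed evaluates \code{expr} with the
#' current stream untouched.
#'
#' @param seed single integer or NULL.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a child seed from a master seed
#'
#' Deterministic arithmetic fan-out (multiplicative-congruential step plus an
#' index offset, modulo 2^31 - 1) so that every (participant, repeat, ...)
#' cell of a simulation gets its own reproducible stream from one master seed.
#'
#' @param seed master seed (integer).
#' @param index non-negative integer offset; distinct indices give distinct
#'   child seeds.
#' @return a single integer in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, index = 0L) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  v <- (s * 48271 + as.numeric(index) * 7919 + 12345) %% m
  as.integer(if (v == 0) 1 else v)
}

#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to unit standard deviation (denominator
#' \code{n - 1}). A constant vector cannot be z-scored and raises an error.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector with mean 0 and sd 1.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Strict upper triangle of a square matrix, as a vector
#' @param m square matrix.
#' @return numeric vector (column-major order, diagonal excluded).
#' @keywords internal
upperTriVec <- function(m) m[upper.tri(m, diag = FALSE)]

#' Pearson correlation with degenerate inputs flagged
#'
#' Returns \code{NA_real_} (the undefined flag) instead of erroring or
#' warning when either input is constant.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or NA if undefined.
#' @keywords internal
safeCor <- function(x, y, method = "pearson") {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}
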