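#' Round half-up
#'
#' Rounds to `digits` decimal places with halves rounded towards
#' +Inf (`0.5 -> 1`, `-0.5 -> 0`), the convention used for all
#' integer-Euro and per-capita reporting in this package.  Base R's
#' `round()` rounds halves to even, which does not reproduce published
#' cost tables.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (default 0).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -52.4468))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

## validation helpers: each names the offending field in its message
check_fraction <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("field '%s': all values must be fractions in [0, 1]", field)
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("field '%s': all values must be finite and >= 0", field)
  }
  invisible(x)
}

check_positive <- function(x, field) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("field '%s': all values must be finite and > 0", field)
  }
  invisible(x)
}

## evaluate `code` under a fixed RNG seed, restoring the caller's
## RNG state afterwards (the synthetic generator's determinism contract)
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
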