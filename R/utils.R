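#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all displayed scores. Base R's
#' [round()] rounds half to even, which would print 6.50 but also turn some
#' exact half boundaries the other way; scorecards instead always display
#' halves rounded up.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(c(6.2879, 6.5, 0.455), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon absorbs representation error in exact rationals (e.g. 2/3)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# format at fixed decimals for file output
fmt2 <- function(x, digits = 2) formatC(round_half_up(x, digits), format = "f", digits = digits)

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a %/% gcd(a, b) * b
}

lcm_all <- function(v) Reduce(lcm2, v, accumulate = FALSE)

# evaluate expr under a fixed RNG seed, restoring global RNG state afterwards
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Parse displayed two-decimal thirds (0, 0.33, 0.67, 1) back to integer
# numerators over `denom`. Errors on values that are not thirds.
thirds_to_numerator <- function(x, denom = 3, tol = 0.005, what = "score") {
  num <- round(x * denom)
  bad <- is.na(x) | num < 0 | num > denom | abs(num / denom - x) > tol + 1e-9
  if (any(bad)) {
    abort(sprintf(
      "%s values must be multiples of 1/%d in [0, 1]; offending value(s): %s",
      what, denom, paste(unique(x[bad]), collapse = ", ")
    ), class = "pmcindex_input_error")
  }
  as.integer(num)
}
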