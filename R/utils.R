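#' Round half away from zero
#'
#' Rounding convention used for all integer percentage summaries: halves are
#' rounded away from zero (so 62.5 -> 63, -1.245 -> -1.25 at 2 digits), unlike
#' [base::round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfAway(c(0.5, 1.5, 2.345), digits = 0)
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. No global state leaks out.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict.lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
  if (strict.lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict.lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

.assertFraction <- function(x, name) .assertScalarNumber(x, name, 0, 1)
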