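#' Round half away from zero
#'
#' Rounds to the nearest integer (or to `digits` decimal places), breaking
#' ties away from zero, so 1440.5 becomes 1441 and -0.5 becomes -1. This is
#' the rounding convention used everywhere the package reports an integer
#' count or a 1-decimal percentage; it differs from [base::round()], which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector, rounded.
#' @examples
#' round_half_away(c(1440.5, 1418.5, -0.5))
#' round_half_away(12.645, digits = 1)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state. All stochastic operations in the package route through this,
# so there is no dependence on global .Random.seed.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Calendar subtraction of whole years from a Date (Feb 29 maps forward per
# seq.Date). Used for the report-eligibility and representativeness windows.
#' @keywords internal
date_minus_years <- function(date, n) {
  seq(date, by = paste0("-", n, " years"), length.out = 2L)[2L]
}

# TRUE when `collection` falls within the closed window
# [analysis - n years, analysis]; whole-day arithmetic, boundaries inclusive.
#' @keywords internal
within_years <- function(collection, analysis, n) {
  !is.na(collection) & collection <= analysis &
    collection >= date_minus_years(analysis, n)
}

#' @keywords internal
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- suppressWarnings(as.Date(as.character(x)))
  d
}
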