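#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all displayed percentages in this package. Base
#' [round()] rounds half to even, which does not reproduce conventional
#' survey-report rounding (e.g. 56.475 must print as 56.48, not 56.47).
#' Internal arithmetic is never rounded; rounding is applied only at the
#' reporting boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(6.619048)   # 6.62
#' round_half_up(0.125, 2)   # 0.13
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # nudge by a few ulps so values stored just under .5 (decimal literals)
  # round as written
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count over a denominator
#'
#' The elementary `100 * k / n` share used throughout survey reporting
#' (reliability fractions, cross-reference coverage, database composition).
#' Kept exact; use `digits` to apply display rounding.
#'
#' @param k Numerator count(s).
#' @param n Denominator count (> 0).
#' @param digits Decimal places for display rounding, or `NULL` for the
#'   exact value.
#' @return Numeric percentage(s).
#' @export
#' @examples
#' share_percent(157, 278)          # 56.47
#' share_percent(157, 278, NULL)    # exact
share_percent <- function(k, n, digits = 2) {
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    abort("`n` must be a single positive count.")
  }
  if (any(k < 0) || any(k > n)) {
    abort("`k` must lie in [0, n].")
  }
  out <- 100 * k / n
  if (is.null(digits)) out else round_half_up(out, digits)
}

# shared input check: single non-negative whole number
assert_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) ||
      x < min || x != trunc(x)) {
    abort(sprintf("`%s` must be a single whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}
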