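#' Rounding conventions used by composition tables
#'
#' Published food-composition tables rarely use round-half-even, so base
#' [round()] cannot reproduce their printed values. These helpers implement
#' the three display conventions the package relies on: round-half-up,
#' truncation toward zero at a fixed number of decimals, and quantization to
#' the nearest quarter unit (ties rounding up).
#'
#' All three add a small epsilon (1e-8) before cutting so that values that
#' are exact decimals mathematically but sit a few ulps below the boundary
#' in floating point (e.g. `15.6/78*100` evaluating just under 20) land on
#' the intended side. Quantities handled here are grams, kilocalories and
#' percentages on a 0--600 scale, where true values never fall within 1e-8
#' of a decimal boundary without being exactly on it.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places to keep.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(122.5, 145.6, 339.6))   # 123 146 340
#' trunc_decimal(c(16.95, 28.717), 1)      # 16.9 28.7
#' round_quarter(c(1.2, 4.243))            # 1.25 4.25
#' @name rounding
NULL

.round_eps <- 1e-8

#' @rdname rounding
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + .round_eps) / p
}

#' @rdname rounding
#' @export
trunc_decimal <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p + sign(x) * .round_eps) / p
}

#' @rdname rounding
#' @export
round_quarter <- function(x) {
  round_half_up(x * 4) / 4
}
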