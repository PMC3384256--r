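`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero,
#' the convention used throughout the package's reported percentages and
#' ratios (base [round()] rounds ties to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard against values like 0.4999999999 that are exact halves
  # up to double precision
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

fmt_num <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
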