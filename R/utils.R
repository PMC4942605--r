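#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the print
#' convention of clinical genetics tables (`round()` in R rounds half to
#' even, which disagrees on values such as 0.5).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared internal: percentage on the printed scale (2 decimals)
fmt_pct <- function(x) round_half_up(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
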