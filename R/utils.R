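#' Round half away from zero
#'
#' Base \code{round} rounds halves to even; the screening-table
#' arithmetic uses conventional half-up rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a reproducible child seed (kept below 2^31) from a base seed
childSeed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}
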