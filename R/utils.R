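#' Round half away from zero
#'
#' Display rounding used throughout the rule reports. Base `round()` rounds
#' half to even; printed clinical tables conventionally round 0.005 up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round(0.125, 2)         # 0.12 (half-to-even)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# itemset key for count lookups ("3 7 12")
.iset_key <- function(ids) paste(ids, collapse = " ")

.msg <- function(...) message("clinrules: ", ...)
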