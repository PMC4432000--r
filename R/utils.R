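#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; tabulated population-genetic
#' summaries conventionally round half up. A small epsilon guards against
#' binary representation of decimal halves (e.g. 0.625 stored as 0.62499...).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# internal: stop with a call-free message
fail <- function(...) stop(..., call. = FALSE)
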