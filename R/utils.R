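#' Round half away from zero
#'
#' Deterministic rounding used everywhere the package maps continuous values
#' to integers (gray rescaling, percent formatting). `round()` in R rounds
#' half to even; half-away-from-zero is used instead so results do not depend
#' on the parity of the integer part.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# internal: stop with a consistent prefix for parameter errors
stop_param <- function(...) stop(..., call. = FALSE)

# internal: coerce to integer scalar with validation
as_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min) {
    stop_param(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
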