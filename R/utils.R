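#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.15 -> 0.2 at one decimal), the
#' convention used for reported percentages. Base \code{round()} rounds half
#' to even, which would print 1.85% of a cohort as 1.8 or 1.9 depending on
#' binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mcec <- function(...) stop(..., call. = FALSE)

assert_in_range <- function(x, lo, hi, what) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop_mcec(sprintf("%s must lie in [%g, %g]", what, lo, hi))
  }
  invisible(x)
}
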