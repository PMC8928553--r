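`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial DoE software and pharmacopoeial reporting round ties away
#' from zero (so 4.85 -> 4.9, -4.85 -> -4.9), unlike base R's
#' round-half-even.  Used whenever package output is compared against a
#' printed, rounded value.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(c(4.85, 3.45, -0.125), 1)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a few ulp so values stored just below a tie (binary fp) still
  # round up, e.g. 4.85 * 10 = 48.49999...
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

stop_aqbd <- function(...) stop(..., call. = FALSE)

assert_named_numeric <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))) || !is.numeric(x))
    stop_aqbd(what, " must be a named numeric vector")
  invisible(x)
}
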