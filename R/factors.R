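#' Define a space of continuous method parameters
#'
#' A factor space lists the controllable chromatographic parameters
#' (critical method parameters, CMPs) with their natural ranges, and
#' fixes the linear coding convention used everywhere else in the
#' package: the natural interval `[low, high]` maps onto the coded
#' interval `[-1, +1]`, with the midpoint at 0.
#'
#' @param name character vector of short factor names (e.g. `"A"`);
#'   must be unique.
#' @param low,high numeric vectors of natural-unit range bounds,
#'   `low < high` elementwise.
#' @param unit character vector of units (optional).
#' @param label character vector of human-readable descriptions
#'   (optional).
#' @return An object of class `factor_space`: a data frame with columns
#'   `name`, `unit`, `label`, `low`, `high`, one row per factor, in the
#'   given (canonical) order.
#' @examples
#' fs <- factor_space(
#'   name = c("A", "D"), low = c(0.2, 2.75), high = c(0.4, 3.75),
#'   unit = c("mL/min", "pH"))
#' code_point(fs, c(A = 0.36, D = 3.5))
#' @seealso [code_point()], [decode_point()], [cabotegravir_factor_space()]
#' @export
factor_space <- function(name, low, high, unit = NA_character_,
                         label = name) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop_aqbd("factor names must be unique")
  low <- as.numeric(low); high <- as.numeric(high)
  if (length(low) != length(name) || length(high) != length(name))
    stop_aqbd("low/high must have one value per factor")
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low >= high))
    stop_aqbd("each factor needs finite low < high")
  out <- data.frame(name = name,
                    unit = rep_len(as.character(unit), length(name)),
                    label = rep_len(as.character(label), length(name)),
                    low = low, high = high,
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_space", "data.frame")
  out
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Factor space (", nrow(x), " factors, coded to [-1, +1]):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

factor_names <- function(space) space$name

as_point_matrix <- function(x, nms) {
  # accept a named vector or a data frame / matrix with factor columns
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    missing <- setdiff(nms, names(x))
    if (length(missing))
      stop_aqbd("missing factor(s): ", paste(missing, collapse = ", "))
    as.matrix(x[nms])
  } else {
    assert_named_numeric(x, "point")
    unknown <- setdiff(names(x), nms)
    if (length(unknown))
      stop_aqbd("unknown factor name(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(nms, names(x))
    if (length(missing))
      stop_aqbd("missing factor(s): ", paste(missing, collapse = ", "))
    matrix(x[nms], nrow = 1, dimnames = list(NULL, nms))
  }
}

point_like_input <- function(m, x) {
  if (is.data.frame(x) || is.matrix(x)) as.data.frame(m) else m[1, ]
}

#' Code natural factor settings to [-1, +1]
#'
#' Applies the linear coding `coded = (x - mid) / half_range` per
#' factor, where `mid = (low + high)/2` and `half_range = (high - low)/2`.
#' In-range natural values map into `[-1, +1]`.
#'
#' @param space a [factor_space()].
#' @param natural a named numeric vector, or a data frame / matrix with
#'   one column per factor (extra columns are an error for vectors,
#'   ignored for data frames).
#' @param strict logical; if `TRUE` (default) an out-of-range value is
#'   an error, otherwise it is coded by extrapolation with a warning.
#' @return Coded values in the same shape as the input (named vector in,
#'   named vector out; data frame in, data frame out).
#' @examples
#' fs <- cabotegravir_factor_space()
#' code_point(fs, c(A = 0.36, B = 55, C = 35, D = 3.5))
#' @export
code_point <- function(space, natural, strict = TRUE) {
  nms <- factor_names(space)
  m <- as_point_matrix(natural, nms)
  mid <- (space$low + space$high) / 2
  half <- (space$high - space$low) / 2
  out_of_range <- sweep(m, 2, space$low, "<") | sweep(m, 2, space$high, ">")
  if (any(out_of_range)) {
    bad <- nms[apply(out_of_range, 2, any)]
    msg <- paste0("value(s) outside natural range for factor(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop_aqbd(msg) else warning(msg, call. = FALSE)
  }
  coded <- sweep(sweep(m, 2, mid, "-"), 2, half, "/")
  point_like_input(coded, natural)
}

#' Decode [-1, +1] factor settings back to natural units
#'
#' Inverse of [code_point()]: `x = mid + coded * half_range`.  Coding is
#' bijective, so `decode_point(space, code_point(space, x))` returns `x`
#' for any in-range `x`.
#'
#' @inheritParams code_point
#' @param coded coded values, same accepted shapes as in [code_point()].
#' @return Natural-unit values, same shape as the input.
#' @export
decode_point <- function(space, coded) {
  nms <- factor_names(space)
  m <- as_point_matrix(coded, nms)
  mid <- (space$low + space$high) / 2
  half <- (space$high - space$low) / 2
  nat <- sweep(sweep(m, 2, half, "*"), 2, mid, "+")
  point_like_input(nat, coded)
}
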