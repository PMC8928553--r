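#' Polynomial term algebra for response-surface models
#'
#' Model terms are written as monomial strings over the factor names:
#' `"1"` is the intercept, `"A"` a main effect, `"A^2"` a pure
#' quadratic, `"A*B"` a two-way interaction, `"A^2*D"` a
#' quadratic-by-linear cross term, `"A*C*D"` a three-way interaction.
#' Factors are separated by `*`, exponents given with `^`.
#'
#' `parse_terms()` converts such strings to exponent maps;
#' `term_label()` is the inverse (factors sorted, exponent 1 implicit).
#'
#' @param terms character vector of monomial strings.
#' @param max_degree maximum allowed total degree (the richest terms in
#'   a practical chromatographic model are quadratic-by-interaction
#'   products such as `A^2*D`, degree 3; degree 4 is the default cap).
#' @return `parse_terms()`: a named list (names are canonical labels) of
#'   named integer vectors mapping factor name to exponent; the
#'   intercept is the empty vector.
#' @examples
#' parse_terms(c("1", "A", "A^2*D", "A*C*D"))
#' @export
parse_terms <- function(terms, max_degree = 4) {
  out <- lapply(terms, function(tt) {
    tt <- gsub(" ", "", tt)
    if (tt == "1" || tt == "")
      return(setNames(integer(0), character(0)))
    parts <- strsplit(tt, "*", fixed = TRUE)[[1]]
    expo <- integer(0)
    for (p in parts) {
      m <- regmatches(p, regexec("^([A-Za-z][A-Za-z0-9_.]*)(\\^([0-9]+))?$", p))[[1]]
      if (length(m) == 0)
        stop_aqbd("cannot parse term '", tt, "'")
      fac <- m[2]
      e <- if (nzchar(m[4])) as.integer(m[4]) else 1L
      expo[fac] <- (if (fac %in% names(expo)) expo[[fac]] else 0L) + e
    }
    if (sum(expo) > max_degree)
      stop_aqbd("term '", tt, "' exceeds maximum degree ", max_degree)
    expo[order(names(expo))]
  })
  names(out) <- vapply(out, term_label, character(1))
  out
}

#' @rdname parse_terms
#' @param exponents a named integer vector mapping factor to exponent.
#' @export
term_label <- function(exponents) {
  if (length(exponents) == 0) return("1")
  exponents <- exponents[order(names(exponents))]
  paste(ifelse(exponents == 1, names(exponents),
               paste0(names(exponents), "^", exponents)),
        collapse = "*")
}

#' Build the model matrix of a polynomial term set
#'
#' Evaluates each monomial at each (coded) design point: entry *(i, j)*
#' is the product over factors of `coded_value^exponent` for term *j*
#' at run *i*.  The intercept column is all ones.
#'
#' @param terms character vector of monomial strings (see
#'   [parse_terms()]), or an already-parsed term list.
#' @param design a data frame or matrix of coded factor settings, one
#'   column per factor.
#' @return A numeric matrix with one row per run and one column per
#'   term, column names being the canonical term labels.
#' @examples
#' d <- data.frame(A = c(-1, 0, 1), B = c(1, 0, -1))
#' model_matrix(c("1", "A", "A^2*B"), d)
#' @export
model_matrix <- function(terms, design) {
  parsed <- if (is.character(terms)) parse_terms(terms) else terms
  design <- as.data.frame(design)
  used <- unique(unlist(lapply(parsed, names)))
  missing <- setdiff(used, names(design))
  if (length(missing))
    stop_aqbd("term(s) reference factor(s) absent from design: ",
              paste(missing, collapse = ", "))
  n <- nrow(design)
  X <- matrix(1, nrow = n, ncol = length(parsed),
              dimnames = list(NULL, names(parsed)))
  for (j in seq_along(parsed)) {
    expo <- parsed[[j]]
    col <- rep(1, n)
    for (fac in names(expo))
      col <- col * design[[fac]]^expo[[fac]]
    X[, j] <- col
  }
  X
}
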