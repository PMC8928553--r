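#' Construct a polynomial response-surface model
#'
#' A response model is a sum of coefficient-times-monomial terms on
#' coded factor units, optionally through a power transform of the
#' response: with `transform = power_transform(lambda)`, the polynomial
#' predicts the transformed response `y^lambda` and natural-scale
#' predictions are obtained by back-transforming `y = value^(1/lambda)`.
#'
#' @param response name of the modelled response (e.g. a resolution).
#' @param coefficients named numeric vector; names are monomial strings
#'   over the factor names (see [parse_terms()]), and exactly one name
#'   must be `"1"` (the intercept).
#' @param transform `"identity"` (default) or [power_transform()].
#' @param anova optional ANOVA summary list (see [anova_stats()]),
#'   with components among `r2`, `adj_r2`, `f_ratio`, `ms_lof`,
#'   `ms_lof_threshold`.
#' @param description optional free-text description.
#' @return An object of class `response_model`.
#' @examples
#' m <- response_model("Rs", c("1" = 3, "A" = 1))
#' evaluate_model(m, c(A = 0.5))
#' @export
response_model <- function(response, coefficients, transform = "identity",
                           anova = NULL, description = NULL) {
  assert_named_numeric(coefficients, "coefficients")
  parsed <- parse_terms(names(coefficients))
  names(coefficients) <- names(parsed)
  if (sum(names(coefficients) == "1") != 1)
    stop_aqbd("model must contain exactly one intercept term \"1\"")
  if (anyDuplicated(names(coefficients)))
    stop_aqbd("duplicated term(s): ",
              paste(unique(names(coefficients)[duplicated(names(coefficients))]),
                    collapse = ", "))
  transform <- validate_transform(transform)
  if (!is.null(anova) && !is.null(anova$r2) && !is.null(anova$adj_r2) &&
      anova$adj_r2 > anova$r2 + 1e-12)
    stop_aqbd("adjusted R^2 cannot exceed R^2")
  structure(list(response = response,
                 coefficients = coefficients,
                 terms = parsed,
                 transform = transform,
                 anova = anova,
                 description = description),
            class = "response_model")
}

#' @rdname response_model
#' @param lambda power-transform exponent (non-zero).
#' @export
power_transform <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda == 0)
    stop_aqbd("lambda must be a single non-zero number")
  list(type = "power", lambda = as.numeric(lambda))
}

validate_transform <- function(transform) {
  if (identical(transform, "identity"))
    return(list(type = "identity"))
  if (is.list(transform) && identical(transform$type, "identity"))
    return(list(type = "identity"))
  if (is.list(transform) && identical(transform$type, "power"))
    return(power_transform(transform$lambda))
  stop_aqbd("transform must be \"identity\" or power_transform(lambda)")
}

forward_transform <- function(y, transform) {
  if (transform$type == "identity") return(y)
  if (any(y <= 0))
    stop_aqbd("power transform requires strictly positive responses")
  y^transform$lambda
}

back_transform <- function(y, transform) {
  if (transform$type == "identity") return(y)
  y^(1 / transform$lambda)
}

#' @export
print.response_model <- function(x, ...) {
  cat("Response-surface model for", x$response, "\n")
  if (!is.null(x$description)) cat("  ", x$description, "\n", sep = "")
  if (x$transform$type == "power")
    cat("  power transform, lambda =", x$transform$lambda,
        "(coefficients on transformed scale)\n")
  co <- x$coefficients
  cat("  ", paste0(formatC(co, format = "fg"), "*(", names(co), ")",
                   collapse = " + "), "\n", sep = "")
  if (!is.null(x$anova)) {
    a <- x$anova
    cat("  R2 =", a$r2, " adj.R2 =", a$adj_r2, " F =", a$f_ratio)
    if (!is.null(a$ms_lof)) cat("  MS-LOF =", a$ms_lof)
    cat("\n")
  }
  invisible(x)
}

#' Evaluate a response model at coded points
#'
#' Computes the polynomial (coefficient times monomial, summed over
#' terms) at each coded point, then back-transforms to the natural
#' response scale if the model carries a power transform.
#'
#' @param model a [response_model()].
#' @param coded a named numeric vector, or a data frame / matrix of
#'   coded factor settings.
#' @param scale `"natural"` (default, back-transformed) or `"model"`
#'   (the raw polynomial value on the transformed scale).
#' @return A numeric vector of predictions (length 1 for a single
#'   point).
#' @examples
#' m <- cabotegravir_models("optimization")$Rs_DP4_HICBG
#' evaluate_model(m, c(A = 0, B = 0, C = 0, D = 0))  # the intercept
#' @export
evaluate_model <- function(model, coded, scale = c("natural", "model")) {
  scale <- match.arg(scale)
  nms <- unique(unlist(lapply(model$terms, names)))
  pt <- if (is.data.frame(coded) || is.matrix(coded)) {
    as.data.frame(coded)
  } else {
    assert_named_numeric(coded, "coded point")
    as.data.frame(as.list(coded))
  }
  missing <- setdiff(nms, names(pt))
  if (length(missing))
    stop_aqbd("coded point lacks factor(s): ", paste(missing, collapse = ", "))
  X <- model_matrix(model$terms, pt)
  y <- drop(X %*% model$coefficients)
  if (scale == "model") y else back_transform(y, model$transform)
}

#' @export
predict.response_model <- function(object, newdata, space = NULL,
                                   scale = c("natural", "model"), ...) {
  if (!is.null(space)) newdata <- code_point(space, newdata)
  evaluate_model(object, newdata, scale = match.arg(scale))
}

# ---- packaged cabotegravir method fixtures --------------------------------

read_model_fixture_file <- function() {
  path <- system.file("extdata", "cabotegravir_models.yaml", package = "aqbd")
  if (!nzchar(path))
    stop_aqbd("packaged model fixture not found; is the package installed?")
  yaml::read_yaml(path)
}

fixture_space <- function(recs) {
  factor_space(name = vapply(recs, `[[`, character(1), "name"),
               low = vapply(recs, `[[`, numeric(1), "low"),
               high = vapply(recs, `[[`, numeric(1), "high"),
               unit = vapply(recs, `[[`, character(1), "unit"),
               label = vapply(recs, `[[`, character(1), "label"))
}

#' Packaged cabotegravir method models and factor spaces
#'
#' `cabotegravir_models()` returns the fitted critical-method-attribute
#' (CMA) models of the cabotegravir UHPLC impurity method as
#' [response_model()] objects: at the optimization stage, the three
#' resolutions `Rs_DP4_HICBG`, `Rs_2CBG_4CBG` and
#' `Rs_4CBG_cabotegravir` as functions of pump flow rate (A), final %
#' mobile phase B (B), column temperature (C) and pH of mobile phase A
#' (D); at the screening stage, peak-count criteria as functions of
#' flow, %B and pH.  `cabotegravir_factor_space()` returns the matching
#' coding convention, `cabotegravir_working_point()` the selected
#' working point (natural units) and `cabotegravir_modr_box()` the
#' established MODR intervals.
#'
#' The `Rs_4CBG_cabotegravir` model is stored with an inverse-square
#' (`lambda = -2`) response transform; its polynomial predicts
#' `Rs^-2` and predictions are back-transformed as `value^(-1/2)`.
#'
#' @param stage `"optimization"` (default) or `"screening"`.
#' @return `cabotegravir_models()`: a named list of
#'   [response_model()]s.  `cabotegravir_factor_space()`: a
#'   [factor_space()].  `cabotegravir_working_point()` a named numeric
#'   vector; `cabotegravir_modr_box()` a named list of `c(low, high)`
#'   ranges.
#' @examples
#' mods <- cabotegravir_models()
#' fs <- cabotegravir_factor_space()
#' wp <- cabotegravir_working_point()
#' sapply(mods, evaluate_model, coded = code_point(fs, wp))
#' @export
cabotegravir_models <- function(stage = c("optimization", "screening")) {
  stage <- match.arg(stage)
  fix <- read_model_fixture_file()
  recs <- fix$models[[stage]]
  mods <- lapply(recs, function(r) {
    response_model(response = r$response,
                   coefficients = unlist(r$coefficients),
                   transform = r$transform,
                   anova = r$anova,
                   description = r$description)
  })
  names(mods) <- vapply(mods, `[[`, character(1), "response")
  mods
}

#' @rdname cabotegravir_models
#' @export
cabotegravir_factor_space <- function(stage = c("optimization", "screening")) {
  stage <- match.arg(stage)
  fixture_space(read_model_fixture_file()$factor_spaces[[stage]])
}

#' @rdname cabotegravir_models
#' @export
cabotegravir_working_point <- function() {
  unlist(read_model_fixture_file()$working_point)
}

#' @rdname cabotegravir_models
#' @export
cabotegravir_modr_box <- function() {
  lapply(read_model_fixture_file()$modr_box, as.numeric)
}
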