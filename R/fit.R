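#' Fit a polynomial response-surface model by ordinary least squares
#'
#' Expands the declared term set into a model matrix on coded units and
#' solves the least-squares problem on the (possibly power-transformed)
#' response scale.  No term selection is performed: the term set is
#' taken as declared.
#'
#' @param design coded design: a data frame with one column per factor
#'   (a `replicate_group` column, if present, is used for the pure
#'   error / lack-of-fit split in [anova_stats()]).
#' @param y numeric response vector, one value per run, on the natural
#'   scale.
#' @param terms character vector of monomial strings including the
#'   intercept `"1"`.
#' @param transform `"identity"` or [power_transform()]; with a power
#'   transform the fit happens on `y^lambda` and predictions are
#'   back-transformed.
#' @param response name used for the fitted [response_model()].
#' @return An object of class `rsm_fit`: `model` (a [response_model()]
#'   with estimated coefficients and ANOVA summary), `residuals` and
#'   `fitted` (transformed scale), `se` (coefficient standard errors),
#'   `sigma2`, `anova` (see [anova_stats()]) and the inputs needed for
#'   prediction.
#' @examples
#' d <- data.frame(A = c(-1, -0.5, 0, 0.5, 1))
#' y <- 0.1 + 0.2 * d$A + 0.9 * d$A^2
#' f <- fit_rsm(d, y, c("1", "A", "A^2"))
#' coef(f)
#' @export
fit_rsm <- function(design, y, terms, transform = "identity",
                    response = "y") {
  design <- as.data.frame(design)
  transform <- validate_transform(transform)
  parsed <- parse_terms(terms)
  if (anyDuplicated(names(parsed)))
    stop_aqbd("duplicated term(s): ",
              paste(unique(names(parsed)[duplicated(names(parsed))]),
                    collapse = ", "))
  X <- model_matrix(parsed, design)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    stop_aqbd("response length (", length(y), ") != number of runs (", n, ")")
  if (anyNA(y))
    stop_aqbd("response contains missing values")
  z <- forward_transform(y, transform)
  qx <- qr(X)
  if (qx$rank < p) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_aqbd("model matrix is rank-deficient; collinear term(s): ",
              paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qx, z)
  fitted <- drop(X %*% beta)
  resid <- z - fitted
  sigma2 <- if (n > p) sum(resid^2) / (n - p) else 0
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  names(se) <- colnames(X)

  fit <- structure(list(
    model = NULL,
    coefficients = setNames(drop(beta), colnames(X)),
    se = se, residuals = resid, fitted = fitted,
    sigma2 = sigma2, n = n, p = p,
    terms = names(parsed), transform = transform,
    response = response, y = y, z = z,
    replicate_group = design$replicate_group %||% NULL
  ), class = "rsm_fit")
  fit$anova <- anova_stats(fit)
  fit$model <- response_model(response, fit$coefficients,
                              transform = transform, anova = fit$anova)
  fit
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  evaluate_model(object$model, newdata, ...)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("OLS response-surface fit:", x$response,
      sprintf("(n = %d runs, p = %d terms)\n", x$n, x$p))
  tab <- data.frame(term = names(x$coefficients),
                    estimate = unname(x$coefficients),
                    std_error = unname(x$se))
  print(tab, row.names = FALSE, digits = 4)
  a <- x$anova
  cat(sprintf("R2 = %.4f  adj.R2 = %.4f  F = %.4f\n",
              a$r2, a$adj_r2, a$f_ratio))
  if (!is.null(a$ms_lof))
    cat(sprintf("MS-LOF = %.4f (threshold %.4f)\n",
                a$ms_lof, a$ms_lof_threshold))
  invisible(x)
}

#' ANOVA diagnostics of a response-surface fit
#'
#' Computes the regression ANOVA summary on the (transformed) fitting
#' scale: `R2 = 1 - SSE/SST`, `adj.R2 = 1 - (1 - R2)(n-1)/(n-p)`, and
#' the overall regression F-ratio `(SSR/(p-1)) / (SSE/(n-p))`.  When
#' the design contains replicate groups (identical factor settings
#' sharing a `replicate_group` label), the residual sum of squares is
#' partitioned into pure error and lack of fit, and the mean-square
#' lack of fit (MS-LOF) is reported together with a threshold
#' `qf(1 - alpha, df_LOF, df_PE) * MS_PE`; `MS-LOF < threshold` is
#' equivalent to a non-significant lack-of-fit F-test at level `alpha`.
#'
#' @param fit an [fit_rsm()] result.
#' @param alpha significance level for the lack-of-fit threshold.
#' @return A list with `r2`, `adj_r2`, `f_ratio`, `df_model`,
#'   `df_resid`, and when replicates exist `ms_lof`,
#'   `ms_lof_threshold`, `ms_pe`, `df_lof`, `df_pe`.
#' @export
anova_stats <- function(fit, alpha = 0.05) {
  z <- fit$z; resid <- fit$residuals
  n <- fit$n; p <- fit$p
  if (n <= p)
    stop_aqbd("no residual degrees of freedom (n <= p)")
  sst <- sum((z - mean(z))^2)
  sse <- sum(resid^2)
  ssr <- sst - sse
  r2 <- if (sst > 0) 1 - sse / sst else 1
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  f_ratio <- if (sse > 0) (ssr / (p - 1)) / (sse / (n - p)) else Inf
  out <- list(r2 = r2, adj_r2 = adj_r2, f_ratio = f_ratio,
              df_model = p - 1, df_resid = n - p)

  rg <- fit$replicate_group
  has_reps <- !is.null(rg) && any(!is.na(rg)) &&
    any(table(rg[!is.na(rg)]) >= 2)
  if (has_reps) {
    groups <- split(seq_len(n)[!is.na(rg)], rg[!is.na(rg)])
    ss_pe <- sum(vapply(groups, function(ix) {
      sum((z[ix] - mean(z[ix]))^2)
    }, numeric(1)))
    df_pe <- sum(vapply(groups, function(ix) length(ix) - 1L, integer(1)))
    df_lof <- (n - p) - df_pe
    if (df_pe > 0 && df_lof > 0) {
      ss_lof <- sse - ss_pe
      ms_pe <- ss_pe / df_pe
      ms_lof <- ss_lof / df_lof
      out$ms_pe <- ms_pe
      out$ms_lof <- ms_lof
      out$df_pe <- df_pe
      out$df_lof <- df_lof
      out$ss_pe <- ss_pe
      out$ss_lof <- ss_lof
      out$ms_lof_threshold <- qf(1 - alpha, df_lof, df_pe) * ms_pe
    }
  } else if (!is.null(rg)) {
    warning("no usable replicate groups; lack-of-fit not computed",
            call. = FALSE)
  }
  out
}

#' Significance screen for a fitted model
#'
#' Accepts a model when its regression F-ratio exceeds the threshold
#' (strictly) and, when a lack-of-fit estimate is present, the
#' mean-square lack of fit stays below its threshold — the acceptance
#' rule used when screening candidate method models.
#'
#' @param anova an ANOVA summary list (from [anova_stats()] or a
#'   packaged model's `anova` field).
#' @param f_threshold minimum F-ratio, default 4.00.
#' @return `TRUE` or `FALSE`.
#' @examples
#' significance_check(list(f_ratio = 39.0792, ms_lof = 0.0153,
#'                         ms_lof_threshold = 0.3917))
#' @export
significance_check <- function(anova, f_threshold = 4.00) {
  ok <- is.finite(anova$f_ratio) && anova$f_ratio > f_threshold
  if (!is.null(anova$ms_lof) && !is.null(anova$ms_lof_threshold))
    ok <- ok && anova$ms_lof < anova$ms_lof_threshold
  isTRUE(ok)
}
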