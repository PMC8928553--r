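#' Candidate grids for optimal design search
#'
#' Builds the finite candidate set from which exchange algorithms pick
#' design runs: the full factorial of the given coded levels per
#' factor, by default the three-level grid `{-1, 0, +1}` (corners,
#' edge/face centres and the centre point).
#'
#' @param factors character vector of factor names, or a
#'   [factor_space()].
#' @param levels numeric vector of coded levels per factor (all within
#'   `[-1, +1]`), or a named list of level vectors per factor.
#' @return A data frame of coded candidate points, one column per
#'   factor.
#' @examples
#' nrow(candidate_grid(c("A", "B")))  # 9
#' @export
candidate_grid <- function(factors, levels = c(-1, 0, 1)) {
  if (inherits(factors, "factor_space")) factors <- factor_names(factors)
  if (!is.list(levels)) levels <- setNames(rep(list(levels), length(factors)),
                                           factors)
  if (any(vapply(levels, function(l) any(abs(l) > 1 + 1e-12), logical(1))))
    stop_aqbd("candidate levels must lie in [-1, +1]")
  g <- expand.grid(levels[factors], KEEP.OUT.ATTRS = FALSE)
  names(g) <- factors
  g
}

info_inverse <- function(X) {
  p <- ncol(X)
  XtX <- crossprod(X)
  inv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(inv) || qr(X)$rank < p)
    stop_aqbd("model matrix is rank-deficient: the design cannot estimate ",
              "all ", p, " terms")
  inv
}

#' A- and G-optimality criteria
#'
#' `a_criterion()` is the average variance of the coefficient
#' estimators at unit error variance, `trace((X'X)^-1) / p`; an
#' A-optimal design minimises it.  `g_criterion()` is the maximum
#' relative prediction variance `x'(X'X)^-1 x` over a candidate set; a
#' G-optimal design minimises the worst predicted-value variance.
#'
#' @param X model matrix of the design (runs x terms), e.g. from
#'   [model_matrix()].
#' @param candidates data frame of coded points over which the
#'   prediction variance is maximised.
#' @param terms term set used to expand `candidates` into model-matrix
#'   rows.
#' @return A single criterion value (smaller is better).
#' @examples
#' X <- model_matrix(c("1", "A"), data.frame(A = c(-1, 1)))
#' a_criterion(X)  # 0.5
#' g_criterion(X, data.frame(A = c(-1, 0, 1)), c("1", "A"))  # 1
#' @export
a_criterion <- function(X) {
  sum(diag(info_inverse(X))) / ncol(X)
}

#' @rdname a_criterion
#' @export
g_criterion <- function(X, candidates, terms) {
  inv <- info_inverse(X)
  Xc <- model_matrix(terms, candidates)
  if (ncol(Xc) != ncol(X))
    stop_aqbd("candidate expansion does not match the design's term set")
  max(rowSums((Xc %*% inv) * Xc))
}

criterion_value <- function(which, X, Xcand) {
  inv <- tryCatch(info_inverse(X), error = function(e) NULL)
  if (is.null(inv)) return(Inf)
  if (which == "A") sum(diag(inv)) / ncol(X)
  else max(rowSums((Xcand %*% inv) * Xcand))
}

#' Select an exact A- or G-optimal design by Fedorov exchange
#'
#' Starts from a random `n_runs`-subset of the candidate set and
#' repeatedly applies the best single swap (replace one design run by
#' one candidate point) until no swap improves the optimality
#' criterion; the whole search is restarted `n_starts` times and the
#' best design kept.  The criterion value is non-increasing across
#' iterations, and with enough starts the exchange attains the
#' exhaustive-enumeration optimum on small instances.  When ranking by
#' the A-criterion, exact ties between starts are broken by the
#' G-criterion, so that a single scalar ordering combining both aims is
#' used.
#'
#' @param terms character vector of monomial strings defining the model
#'   to be estimated.
#' @param candidates data frame of coded candidate points (see
#'   [candidate_grid()]).
#' @param n_runs number of runs in the design; must be at least the
#'   number of terms.
#' @param criterion `"A"` (default) or `"G"`.
#' @param n_starts number of random restarts.
#' @param seed integer seed making the search reproducible.
#' @param center_replicates number of centre-point replicate runs
#'   appended after optimisation (labelled by `replicate_group`), so
#'   that pure error and lack-of-fit are estimable; 0 to disable.
#' @return A list of class `doe_design`: `design` (coded data frame
#'   with `run_id` and `replicate_group`), `criterion`, `value`, and
#'   `terms`.
#' @examples
#' d <- exchange_design(c("1", "A"), data.frame(A = c(-1, 0, 1)),
#'                      n_runs = 2, seed = 1, center_replicates = 0)
#' d$design
#' @export
exchange_design <- function(terms, candidates, n_runs,
                            criterion = c("A", "G"), n_starts = 10,
                            seed = NULL, center_replicates = 3) {
  criterion <- match.arg(criterion)
  candidates <- as.data.frame(candidates)
  parsed <- parse_terms(terms)
  p <- length(parsed)
  nc <- nrow(candidates)
  if (n_runs < p)
    stop_aqbd("n_runs (", n_runs, ") is below the number of terms (", p, ")")
  if (n_runs > nc)
    stop_aqbd("n_runs exceeds the number of candidate points")
  Xcand <- model_matrix(parsed, candidates)
  if (!is.null(seed)) set.seed(seed)

  eval_subset <- function(idx) criterion_value(criterion, Xcand[idx, , drop = FALSE], Xcand)

  best <- NULL
  for (s in seq_len(n_starts)) {
    idx <- sample.int(nc, n_runs)
    val <- eval_subset(idx)
    if (n_runs < nc) {
      repeat {
        improved <- FALSE
        for (i in seq_len(n_runs)) {
          pool <- setdiff(seq_len(nc), idx)
          trial <- idx
          vals <- vapply(pool, function(j) {
            trial[i] <- j
            eval_subset(trial)
          }, numeric(1))
          jbest <- which.min(vals)
          if (vals[jbest] < val - 1e-12) {
            idx[i] <- pool[jbest]
            val <- vals[jbest]
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    tie_val <- if (is.finite(val) && criterion == "A")
      criterion_value("G", Xcand[idx, , drop = FALSE], Xcand) else val
    cand <- list(idx = sort(idx), value = val, tie = tie_val)
    if (is.null(best) || cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) <= 1e-12 && cand$tie < best$tie - 1e-12))
      best <- cand
  }
  if (!is.finite(best$value))
    stop_aqbd("all random starts produced singular designs; ",
              "enlarge the candidate set or n_runs")

  design <- candidates[best$idx, , drop = FALSE]
  rownames(design) <- NULL
  design$replicate_group <- NA_integer_
  if (center_replicates > 0) {
    center <- as.data.frame(as.list(setNames(rep(0, ncol(candidates)),
                                             names(candidates))))
    reps <- center[rep(1, center_replicates), , drop = FALSE]
    reps$replicate_group <- 1L
    design <- rbind(design, reps)
  }
  design <- cbind(run_id = seq_len(nrow(design)), design)
  rownames(design) <- NULL
  structure(list(design = design, criterion = criterion,
                 value = best$value, terms = names(parsed)),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat("Exchange design:", nrow(x$design), "runs,", length(x$terms),
      "terms, ", x$criterion, "-criterion = ", format(x$value), "\n", sep = "")
  print(utils::head(x$design, 12))
  if (nrow(x$design) > 12) cat("...\n")
  invisible(x)
}

#' Attach natural-unit columns to a coded design
#'
#' @param design a `doe_design` or a coded data frame.
#' @param space a [factor_space()].
#' @return A data frame with `run_id`, natural-unit factor columns,
#'   `replicate_group`, and the coded columns prefixed `coded_`.
#' @export
design_table <- function(design, space) {
  d <- if (inherits(design, "doe_design")) design$design else as.data.frame(design)
  nms <- factor_names(space)
  coded <- d[nms]
  natural <- decode_point(space, coded)
  out <- data.frame(run_id = d$run_id %||% seq_len(nrow(d)), natural,
                    replicate_group = d$replicate_group %||% NA_integer_)
  names(coded) <- paste0("coded_", nms)
  cbind(out, coded)
}
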