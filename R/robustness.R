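#' Process-capability index against a lower specification limit
#'
#' `cpk()` is the one-sided process-capability index
#' `(mean - lsl) / (3 * sd)`: the distance of the process mean from
#' the lower specification limit in units of three standard
#' deviations.  With a degenerate zero spread the index is capped at
#' `cap` when the mean clears the limit and is 0 otherwise.
#'
#' `coverage_for_cpk()` converts a capability index to the percentage
#' of a normal population falling within `+/- 3 * cpk` standard
#' deviations of its mean (e.g. 99.99% at 1.33, 99.73% at 1.0).
#'
#' @param mean,sd sample mean and standard deviation of the simulated
#'   response.
#' @param lsl lower specification limit of the response.
#' @param cap value returned when `sd == 0` and `mean > lsl`.
#' @return `cpk()`: a single capability index; `coverage_for_cpk()`:
#'   a percentage.
#' @examples
#' cpk(3.0, 0.25, 2.0)          # 1.333...
#' coverage_for_cpk(1.33)       # 99.99 (to two decimals)
#' @export
cpk <- function(mean, sd, lsl, cap = 999) {
  if (sd < 0) stop_aqbd("sd must be non-negative")
  if (sd == 0) return(if (mean > lsl) cap else 0)
  (mean - lsl) / (3 * sd)
}

#' @rdname cpk
#' @export
coverage_for_cpk <- function(cpk) {
  if (any(cpk < 0)) stop_aqbd("cpk must be non-negative")
  (2 * pnorm(3 * cpk) - 1) * 100
}

#' Specify random perturbations of the method parameters
#'
#' Describes the run-to-run wobble of the controllable parameters used
#' by the Monte-Carlo robustness simulation: independent normal
#' perturbations in natural units, truncated to the factor ranges by
#' reject-and-redraw.  The default standard deviations reflect typical
#' instrument tolerances: 0.01 mL/min on flow, 0.5 %-points on the
#' gradient endpoint, 0.5 degC on column temperature and 0.05 pH units.
#'
#' @param sd named numeric vector of per-factor standard deviations in
#'   natural units (names must match the factor space; 0 disables the
#'   perturbation of a factor).
#' @param n_draws number of Monte-Carlo draws (at least 100).
#' @param seed integer seed for reproducibility.
#' @return An object of class `perturbation_spec`.
#' @examples
#' perturbation_spec(c(A = 0.01, B = 0.5, C = 0.5, D = 0.05), seed = 1)
#' @export
perturbation_spec <- function(sd = c(A = 0.01, B = 0.5, C = 0.5, D = 0.05),
                              n_draws = 10000, seed = NULL) {
  assert_named_numeric(sd, "sd")
  if (any(sd < 0)) stop_aqbd("perturbation sds must be non-negative")
  if (n_draws < 100) stop_aqbd("n_draws must be at least 100")
  structure(list(sd = sd, n_draws = as.integer(n_draws), seed = seed),
            class = "perturbation_spec")
}

# draw n perturbed copies of each row of `nominal` (natural units),
# truncated to the factor ranges by reject-and-redraw
draw_perturbed <- function(nominal, space, pert) {
  nms <- factor_names(space)
  n <- nrow(nominal) * pert$n_draws
  out <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    mu <- rep(nominal[, nms[j]], each = pert$n_draws)
    s <- pert$sd[[nms[j]]] %||% 0
    if (is.na(s)) s <- 0
    if (s == 0) { out[, j] <- mu; next }
    lo <- space$low[j]; hi <- space$high[j]
    if (any(mu < lo) || any(mu > hi))
      stop_aqbd("nominal point outside the natural range of factor ", nms[j])
    x <- rnorm(n, mu, s)
    for (it in 1:1000) {
      bad <- which(x < lo | x > hi)
      if (!length(bad)) break
      x[bad] <- rnorm(length(bad), mu[bad], s)
    }
    if (any(x < lo | x > hi))
      stop_aqbd("could not draw in-range perturbations for factor ", nms[j])
    out[, j] <- x
  }
  out
}

#' Monte-Carlo capability of a response model at a nominal point
#'
#' Draws perturbed factor settings around the nominal operating point
#' (independent truncated normals, see [perturbation_spec()]),
#' evaluates the response model at each draw, and summarises the
#' simulated response distribution as a [cpk()] against the CMA lower
#' limit.
#'
#' @param model a [response_model()].
#' @param nominal named numeric vector of natural-unit factor settings.
#' @param pert a [perturbation_spec()].
#' @param space the [factor_space()] defining coding and ranges.
#' @param lsl lower specification limit of the response (e.g. 2.0 for
#'   a chromatographic resolution).
#' @return A list with `mean`, `sd`, `cpk`, `n_draws`.
#' @examples
#' fs <- cabotegravir_factor_space()
#' m <- cabotegravir_models()$Rs_DP4_HICBG
#' monte_carlo_cpk(m, cabotegravir_working_point(),
#'                 perturbation_spec(n_draws = 1000, seed = 1), fs)
#' @export
monte_carlo_cpk <- function(model, nominal, pert, space, lsl = 2.0) {
  stopifnot(inherits(pert, "perturbation_spec"))
  nom <- as_point_matrix(nominal, factor_names(space))
  if (!is.null(pert$seed)) set.seed(pert$seed)
  draws <- draw_perturbed(nom, space, pert)
  y <- evaluate_model(model, code_point(space, as.data.frame(draws)))
  m <- mean(y); s <- sd(y)
  list(mean = m, sd = s, cpk = cpk(m, s, lsl), n_draws = pert$n_draws)
}

# ---- MODR mapping ---------------------------------------------------------

#' Map the Method Operable Design Region over a factor grid
#'
#' Evaluates every CMA model on a regular grid of natural-unit factor
#' settings, optionally runs the Monte-Carlo capability simulation at
#' each node, and flags the nodes where every CMA prediction meets its
#' lower limit (and, when simulated, every Cpk meets `cpk_min`).  The
#' largest axis-aligned all-pass box of grid nodes is extracted by
#' exhaustive search over grid-aligned boxes (ties broken by larger
#' natural volume, then lexicographic lower corner).
#'
#' @param models named list of [response_model()]s.
#' @param space a [factor_space()].
#' @param box named list of natural `c(low, high)` intervals per factor
#'   delimiting the mapped region (default: the full factor ranges).
#' @param levels number of grid levels per factor (default 9).
#' @param threshold lower specification limit per CMA: a single number
#'   or a named vector by response.
#' @param pert optional [perturbation_spec()]; when supplied, per-node
#'   Cpk values are simulated and gate the pass mask.
#' @param cpk_min minimum acceptable capability index (default 1.33).
#' @return An object of class `modr_result`: `grid` (natural units),
#'   `coded`, `predictions` (matrix node x CMA), `cpk` (or `NULL`),
#'   `pass` (logical), `box` (named list of natural intervals, or
#'   `NULL` when nothing passes), `levels`, `threshold`, `cpk_min`.
#' @examples
#' mods <- cabotegravir_models()
#' fs <- cabotegravir_factor_space()
#' res <- map_modr(mods, fs, box = cabotegravir_modr_box(), levels = 5)
#' all(res$pass)
#' @export
map_modr <- function(models, space, box = NULL, levels = 9,
                     threshold = 2.0, pert = NULL, cpk_min = 1.33) {
  nms <- factor_names(space)
  box <- box %||% setNames(lapply(seq_along(nms), function(i)
    c(space$low[i], space$high[i])), nms)
  if (!all(nms %in% names(box)))
    stop_aqbd("box must provide an interval for every factor")
  axis_levels <- lapply(nms, function(f)
    seq(box[[f]][1], box[[f]][2], length.out = levels))
  names(axis_levels) <- nms
  grid <- expand.grid(axis_levels, KEEP.OUT.ATTRS = FALSE)
  coded <- code_point(space, grid)

  thr <- if (length(threshold) == 1 && is.null(names(threshold)))
    setNames(rep(threshold, length(models)), names(models))
  else threshold
  missing <- setdiff(names(models), names(thr))
  if (length(missing))
    stop_aqbd("no threshold for model(s): ", paste(missing, collapse = ", "))

  pred <- vapply(models, evaluate_model, numeric(nrow(grid)), coded = coded)
  pred <- matrix(pred, nrow = nrow(grid),
                 dimnames = list(NULL, names(models)))
  pass <- rowSums(sweep(pred, 2, thr[colnames(pred)], "<")) == 0

  cpk_mat <- NULL
  if (!is.null(pert)) {
    stopifnot(inherits(pert, "perturbation_spec"))
    if (!is.null(pert$seed)) set.seed(pert$seed)
    cpk_mat <- matrix(NA_real_, nrow(grid), length(models),
                      dimnames = list(NULL, names(models)))
    chunk <- max(1L, floor(2e5 / pert$n_draws))
    starts <- seq(1, nrow(grid), by = chunk)
    for (s in starts) {
      ix <- s:min(s + chunk - 1, nrow(grid))
      draws <- draw_perturbed(as.matrix(grid[ix, , drop = FALSE]), space, pert)
      cdraws <- code_point(space, as.data.frame(draws))
      for (mname in names(models)) {
        y <- matrix(evaluate_model(models[[mname]], cdraws),
                    nrow = pert$n_draws)
        mu <- colMeans(y)
        sdv <- apply(y, 2, sd)
        cpk_mat[ix, mname] <- mapply(cpk, mu, sdv,
                                     MoreArgs = list(lsl = thr[[mname]]))
      }
    }
    pass <- pass & rowSums(cpk_mat < cpk_min) == 0
  }

  if (!any(pass))
    warning("no grid node satisfies all criteria; MODR box is empty",
            call. = FALSE)
  box_out <- if (any(pass))
    extract_max_box(array(pass, dim = rep(levels, length(nms))), axis_levels)
  else NULL

  structure(list(grid = grid, coded = coded, predictions = pred,
                 cpk = cpk_mat, pass = pass, box = box_out,
                 levels = axis_levels, threshold = thr,
                 cpk_min = if (is.null(pert)) NULL else cpk_min),
            class = "modr_result")
}

#' @export
print.modr_result <- function(x, ...) {
  cat("MODR map:", nrow(x$grid), "grid nodes,",
      sum(x$pass), "pass all criteria\n")
  if (!is.null(x$box)) {
    cat("Largest all-pass box (natural units):\n")
    for (f in names(x$box))
      cat(sprintf("  %s: [%g, %g]\n", f, x$box[[f]][1], x$box[[f]][2]))
  } else cat("No all-pass box.\n")
  invisible(x)
}

#' @export
as.data.frame.modr_result <- function(x, ...) {
  out <- cbind(x$grid, as.data.frame(x$predictions))
  if (!is.null(x$cpk)) {
    cpk_df <- as.data.frame(x$cpk)
    names(cpk_df) <- paste0("cpk_", names(cpk_df))
    out <- cbind(out, cpk_df)
  }
  out$pass <- x$pass
  out
}

#' Largest all-TRUE axis-aligned box in a logical grid
#'
#' Exhaustively scores every grid-aligned box (all pairs of lower and
#' upper level indices per dimension) via a k-dimensional cumulative
#' sum, keeping the box whose nodes are all `TRUE` and whose
#' natural-unit volume is largest; ties go to the lexicographically
#' smallest lower corner.
#'
#' @param pass a logical array (one cell per grid node).
#' @param axis_levels named list of the natural-unit level values along
#'   each dimension.
#' @return Named list of `c(low, high)` natural intervals, or `NULL`
#'   if no cell is `TRUE`.
#' @export
extract_max_box <- function(pass, axis_levels) {
  dims <- dim(pass) %||% length(pass)
  k <- length(dims)
  if (!any(pass)) return(NULL)
  if (is.null(dim(pass))) dim(pass) <- dims

  # padded k-dimensional cumulative count of passing nodes:
  # cs[i1+1, ..., ik+1] = number of TRUE cells with index <= (i1, ..., ik)
  cs <- array(0, dims + 1L)
  cs <- do.call(`[<-`, c(list(cs), lapply(dims, function(n) 2:(n + 1L)),
                         list(array(as.numeric(pass), dims))))
  cum_along <- function(a, d) {
    perm <- c(d, setdiff(seq_len(k), d))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    m <- apply(m, 2, cumsum)
    dim(m) <- dp
    aperm(m, order(perm))
  }
  for (d in seq_len(k)) cs <- cum_along(cs, d)

  box_count <- function(lo, hi) {
    # inclusion-exclusion over the 2^k corners of the padded array
    cnt <- numeric(nrow(lo))
    for (ci in seq_len(2^k)) {
      take_lo <- as.logical(bitwAnd(ci - 1L, 2L^(seq_len(k) - 1L)) > 0)
      idx <- matrix(0L, nrow(lo), k)
      for (d in seq_len(k))
        idx[, d] <- if (take_lo[d]) lo[, d] else hi[, d] + 1L
      lin <- idx[, 1]
      mult <- 1
      for (d in seq_len(k)[-1]) {
        mult <- mult * (dims[d - 1] + 1L)
        lin <- lin + (idx[, d] - 1L) * mult
      }
      cnt <- cnt + (-1)^sum(take_lo) * cs[lin]
    }
    cnt
  }

  pairs <- lapply(seq_len(k), function(d) {
    pr <- expand.grid(lo = seq_len(dims[d]), hi = seq_len(dims[d]))
    pr[pr$lo <= pr$hi, , drop = FALSE]
  })
  lex_less <- function(a, b) {
    for (d in seq_along(a)) {
      if (a[d] < b[d]) return(TRUE)
      if (a[d] > b[d]) return(FALSE)
    }
    FALSE
  }

  best <- NULL
  rest <- if (k >= 2)
    expand.grid(lapply(pairs[-1], function(p) seq_len(nrow(p))))
  else data.frame(row.names = 1)
  for (i1 in seq_len(nrow(pairs[[1]]))) {  # chunk on dim 1 to bound memory
    nrest <- nrow(rest)
    lo <- matrix(0L, nrest, k); hi <- matrix(0L, nrest, k)
    lo[, 1] <- pairs[[1]]$lo[i1]; hi[, 1] <- pairs[[1]]$hi[i1]
    if (k >= 2) for (d in 2:k) {
      lo[, d] <- pairs[[d]]$lo[rest[[d - 1]]]
      hi[, d] <- pairs[[d]]$hi[rest[[d - 1]]]
    }
    cnt <- box_count(lo, hi)
    size <- apply(hi - lo + 1L, 1, prod)
    ok <- which(abs(cnt - size) < 0.5)  # all nodes in the box pass
    if (!length(ok)) next
    vol <- rep(1, length(ok))
    for (d in seq_len(k)) {
      lv <- axis_levels[[d]]
      vol <- vol * (lv[hi[ok, d]] - lv[lo[ok, d]])
    }
    keys <- c(list(-vol), lapply(seq_len(k), function(d) lo[ok, d]))
    j <- ok[do.call(order, keys)[1]]
    jvol <- vol[match(j, ok)]
    cand <- list(lo = lo[j, ], hi = hi[j, ], vol = jvol)
    if (is.null(best) || cand$vol > best$vol + 1e-12 ||
        (abs(cand$vol - best$vol) <= 1e-12 && lex_less(cand$lo, best$lo)))
      best <- cand
  }
  out <- lapply(seq_len(k), function(d) {
    lv <- axis_levels[[d]]
    c(lv[best$lo[d]], lv[best$hi[d]])
  })
  names(out) <- names(axis_levels)
  out
}

#' Predicted CMA values at an operating point
#'
#' Evaluates every CMA model at a natural-unit operating point and
#' reports full-precision predictions alongside a copy rounded to one
#' decimal (ties away from zero), matching the convention of printed
#' method-development reports.
#'
#' @param models named list of [response_model()]s.
#' @param point named numeric vector in natural units.
#' @param space a [factor_space()].
#' @return A data frame with columns `response`, `prediction`,
#'   `rounded`.
#' @examples
#' working_point_report(cabotegravir_models(),
#'                      cabotegravir_working_point(),
#'                      cabotegravir_factor_space())
#' @export
working_point_report <- function(models, point, space) {
  coded <- code_point(space, point)
  pred <- vapply(models, evaluate_model, numeric(1), coded = coded)
  data.frame(response = names(models),
             prediction = unname(pred),
             rounded = round_half_away(unname(pred), 1),
             row.names = NULL)
}
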