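#' Linear desirability rules
#'
#' Grades a measured or predicted criterion on a 0-1 desirability
#' scale by linear interpolation between two anchors: the value mapped
#' to 0 and the value mapped to 1 (clamped outside).  The direction is
#' implied by the anchors — e.g. with `anchor_zero = 8` resolved peaks
#' and `anchor_one = 10`, more peaks is better.
#'
#' @param criterion name of the graded criterion.
#' @param anchor_zero value mapped to desirability 0.
#' @param anchor_one value mapped to desirability 1 (must differ from
#'   `anchor_zero`).
#' @param weight positive weight used by [cumulative_desirability()].
#' @return An object of class `desirability_rule`.
#' @examples
#' r <- desirability_rule("n_peaks", 8, 10)
#' desirability_score(r, c(7, 9, 10.5))
#' @export
desirability_rule <- function(criterion, anchor_zero, anchor_one,
                              weight = 1) {
  if (anchor_zero == anchor_one)
    stop_aqbd("anchors must differ")
  if (weight <= 0)
    stop_aqbd("weight must be positive")
  structure(list(criterion = criterion, anchor_zero = anchor_zero,
                 anchor_one = anchor_one, weight = weight),
            class = "desirability_rule")
}

#' @rdname desirability_rule
#' @param rule a [desirability_rule()].
#' @param value numeric vector of criterion values.
#' @export
desirability_score <- function(rule, value) {
  d <- (value - rule$anchor_zero) / (rule$anchor_one - rule$anchor_zero)
  pmin(pmax(d, 0), 1)
}

#' Cumulative desirability over several criteria
#'
#' The weighted geometric mean of the per-criterion scores,
#' `exp(sum(w_i log d_i) / sum(w_i))`; a single zero score annihilates
#' the product, so any fully undesirable criterion vetoes the
#' candidate.
#'
#' @param scores numeric vector of per-criterion desirabilities in
#'   `[0, 1]`.
#' @param weights optional positive weights (default equal).
#' @return A single value in `[0, 1]`.
#' @examples
#' cumulative_desirability(c(0.5, 0.72))  # sqrt(0.36) = 0.6
#' @export
cumulative_desirability <- function(scores, weights = NULL) {
  if (length(scores) == 0)
    stop_aqbd("at least one desirability score is required")
  if (any(scores < 0 | scores > 1))
    stop_aqbd("scores must lie in [0, 1]")
  weights <- weights %||% rep(1, length(scores))
  if (length(weights) != length(scores) || any(weights <= 0))
    stop_aqbd("weights must be positive and match the scores")
  if (any(scores == 0)) return(0)
  exp(sum(weights * log(scores)) / sum(weights))
}

#' Search a grid for the most desirable operating point
#'
#' Evaluates every candidate point under every criterion's response
#' model, grades each prediction with its desirability rule, combines
#' them by [cumulative_desirability()], and returns the best point.
#' Ties are broken deterministically by lexicographic coded
#' coordinates.
#'
#' @param models named list of [response_model()]s, one per rule
#'   criterion.
#' @param rules list of [desirability_rule()]s.
#' @param grid data frame of coded candidate points.
#' @return A list with `point` (one-row data frame of coded
#'   coordinates), `score`, and `scores` (the full per-point cumulative
#'   desirability vector).
#' @export
best_answer_search <- function(models, rules, grid) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0)
    stop_aqbd("candidate grid is empty")
  missing <- setdiff(vapply(rules, `[[`, character(1), "criterion"),
                     names(models))
  if (length(missing))
    stop_aqbd("no model for criterion/criteria: ",
              paste(missing, collapse = ", "))
  per_rule <- vapply(rules, function(r) {
    desirability_score(r, evaluate_model(models[[r$criterion]], grid))
  }, numeric(nrow(grid)))
  per_rule <- matrix(per_rule, nrow = nrow(grid))
  w <- vapply(rules, `[[`, numeric(1), "weight")
  scores <- apply(per_rule, 1, cumulative_desirability, weights = w)
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1) {  # lexicographic coded tie-break
    ord <- do.call(order, as.list(grid[cand, , drop = FALSE]))
    cand <- cand[ord]
  }
  list(point = grid[cand[1], , drop = FALSE],
       score = scores[cand[1]],
       scores = scores)
}
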