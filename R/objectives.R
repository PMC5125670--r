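#' Pheromone transforms and cost functions for short-form optimization
#'
#' The ant-colony selector scores a candidate item subset by summing four
#' criterion-specific "pheromone" components, each a logistic (or, for
#' sensitivity, quadratic) transform centred on a conventional cutoff so
#' that a candidate sitting exactly at the cutoff scores 0.5 (1.0 for
#' sensitivity) and differences near the cutoff count for more than
#' differences in the tails:
#'
#' * `phi_cfi(cfi)` = 1 / (1 + exp(95 - 100 CFI)); midpoint at CFI = .95.
#' * `phi_rmsea(rmsea)` = 1 - 1 / (1 + exp(5 - 100 RMSEA)); midpoint at .05.
#' * `phi_fit` = mean of the two fit pheromones.
#' * `phi_rel(omega)` = 1 / (1 + exp(9 - 10 omega)); midpoint at omega = .90.
#' * `phi_sens(m)` = -5 (m - .625)^2 + 1, maximal when the mean item
#'   difficulty (proportion correct) is .625, the midpoint between a .25
#'   guessing floor and 1; optionally clamped below at 0 so it cannot
#'   dominate the sum with large negative values.
#' * `phi_cor(d)` = 1 - 1 / (1 + exp(3 - 100 d)) where `d` is the maximum
#'   absolute change, across a covariate panel, between the short-form and
#'   long-form sum-score Pearson correlations; midpoint at .03.
#'
#' All logistic transforms are evaluated with [stats::plogis()], which is
#' overflow-safe for extreme arguments.
#'
#' @param cfi Comparative Fit Index, in \[0, 1\].
#' @param rmsea Root Mean Square Error of Approximation, nonnegative.
#' @param phi_cfi,phi_rmsea for `phi_fit()`: the two fit pheromone levels.
#' @param omega McDonald's omega reliability, in \[0, 1\].
#' @param mean_difficulty mean proportion correct of the subset, in \[0, 1\].
#' @param clamp clamp the sensitivity pheromone below at 0 (default TRUE).
#' @param max_abs_diff largest absolute covariate-correlation change, in
#'   \[0, 2\].
#' @return The pheromone level (vectorized over the input).
#' @seealso [total_objective()], [ga_cost()]
#' @name pheromones
NULL

#' @rdname pheromones
#' @export
phi_cfi <- function(cfi) {
  if (any(is.na(cfi)) || any(cfi < 0 | cfi > 1)) {
    stop("`cfi` must lie in [0, 1]", call. = FALSE)
  }
  stats::plogis(100 * cfi - 95)
}

#' @rdname pheromones
#' @export
phi_rmsea <- function(rmsea) {
  if (any(is.na(rmsea)) || any(rmsea < 0)) {
    stop("`rmsea` must be nonnegative", call. = FALSE)
  }
  stats::plogis(5 - 100 * rmsea)
}

#' @rdname pheromones
#' @export
phi_fit <- function(phi_cfi, phi_rmsea) (phi_cfi + phi_rmsea) / 2

#' @rdname pheromones
#' @export
phi_rel <- function(omega) {
  if (any(is.na(omega)) || any(omega < 0 | omega > 1)) {
    stop("`omega` must lie in [0, 1]", call. = FALSE)
  }
  stats::plogis(10 * omega - 9)
}

#' @rdname pheromones
#' @export
phi_sens <- function(mean_difficulty, clamp = TRUE) {
  if (any(is.na(mean_difficulty)) ||
      any(mean_difficulty < 0 | mean_difficulty > 1)) {
    stop("`mean_difficulty` must lie in [0, 1]", call. = FALSE)
  }
  v <- -5 * (mean_difficulty - 0.625)^2 + 1
  if (clamp) v <- pmax(v, 0)
  v
}

#' @rdname pheromones
#' @export
phi_cor <- function(max_abs_diff) {
  if (any(is.na(max_abs_diff)) ||
      any(max_abs_diff < 0 | max_abs_diff > 2)) {
    stop("`max_abs_diff` must lie in [0, 2]", call. = FALSE)
  }
  stats::plogis(3 - 100 * max_abs_diff)
}

#' Combine pheromone components into the selection objective
#'
#' Builds a `pheromone_components` record from fit indices, reliability,
#' mean difficulty and covariate-correlation change, and sums the four
#' criteria (fit, reliability, sensitivity, correlation preservation) with
#' equal weight. The ant-colony selector maximizes this total; with the
#' sensitivity term clamped at 0 the supremum is 4.
#'
#' @inheritParams pheromones
#' @return An object of class `pheromone_components`: a list with the five
#'   component levels, `phi_fit`, the `total`, and the clamping mode used.
#' @examples
#' pc <- pheromone_components(cfi = 0.95, rmsea = 0.05, omega = 0.9,
#'                            mean_difficulty = 0.625, max_abs_diff = 0.03)
#' pc$total # 2.5: every criterion exactly at its cutoff
#' @export
pheromone_components <- function(cfi, rmsea, omega, mean_difficulty,
                                 max_abs_diff, clamp = TRUE) {
  p_cfi <- phi_cfi(cfi)
  p_rmsea <- phi_rmsea(rmsea)
  comp <- list(
    phi_cfi = p_cfi,
    phi_rmsea = p_rmsea,
    phi_fit = phi_fit(p_cfi, p_rmsea),
    phi_rel = phi_rel(omega),
    phi_sens = phi_sens(mean_difficulty, clamp = clamp),
    phi_cor = phi_cor(max_abs_diff),
    clamped = clamp
  )
  comp$total <- comp$phi_fit + comp$phi_rel + comp$phi_sens + comp$phi_cor
  class(comp) <- "pheromone_components"
  comp
}

#' @rdname pheromone_components
#' @param components a `pheromone_components` object.
#' @export
total_objective <- function(components) {
  with(components, phi_fit + phi_rel + phi_sens + phi_cor)
}

#' @export
print.pheromone_components <- function(x, ...) {
  cat("Pheromone components", if (x$clamped) "(sensitivity clamped at 0)",
      "\n")
  v <- unlist(x[c("phi_fit", "phi_rel", "phi_sens", "phi_cor", "total")])
  print(round(v, 4))
  invisible(x)
}

#' Genetic-algorithm cost for a candidate short form
#'
#' `cost = I * k + (1 - R^2)`: a fixed cost `I` per retained item plus the
#' share of long-form total-score variance the retained items fail to
#' explain. Larger `I` buys brevity at the expense of comprehensiveness;
#' `I = 0` removes all pressure to shorten.
#'
#' @param item_cost_I nonnegative fixed cost per retained item.
#' @param k number of items retained.
#' @param r_squared squared multiple correlation from regressing the
#'   long-form total score on the retained items' scores, in \[0, 1\].
#' @return The scalar cost (lower is better).
#' @examples
#' ga_cost(0.05, k = 20, r_squared = 0.95) # 1.05
#' @export
ga_cost <- function(item_cost_I, k, r_squared) {
  if (any(item_cost_I < 0)) stop("`item_cost_I` must be >= 0", call. = FALSE)
  if (any(k < 1)) stop("`k` must be >= 1", call. = FALSE)
  if (any(r_squared < 0 | r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1]", call. = FALSE)
  }
  item_cost_I * k + (1 - r_squared)
}
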