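#' Configuration for ant colony optimization
#'
#' Hyperparameters of the pheromone-guided subset search. Defaults follow
#' common practice for ACO item selection: 30 ants per iteration,
#' evaporation rate .1, deposit on the iteration-best subset proportional to
#' its objective value, and three independent replications with derived
#' seeds of which the best (highest pheromone objective) is reported.
#'
#' @param k target short-form length.
#' @param n_ants subsets sampled per iteration.
#' @param evaporation_rate pheromone decay rate in (0, 1).
#' @param deposit_scale multiplier on the deposited scores.
#' @param deposit_rule `"iteration_best"` (default): only the iteration's
#'   best subset deposits, proportionally to its score — the strongly
#'   exploitative rule used for scale abbreviation. `"all_ants"`: every ant
#'   deposits its score scaled by `deposit_scale / n_ants` on its items, the
#'   classic ant-system rule; its reinforcement is balanced, so a flat
#'   objective leaves the pheromone uniform up to sampling noise, whereas
#'   under `"iteration_best"` a flat objective still concentrates pheromone
#'   (whichever subset is drawn first is reinforced and drawn again).
#' @param max_iterations iteration cap per replication.
#' @param stall_limit iterations without improvement before stopping.
#' @param n_replications independent seeded runs; the best is returned.
#' @param clamp_sens clamp the sensitivity pheromone below at 0.
#' @param seed master seed; replication r uses `seed + r`.
#' @return An object of class `aco_config`.
#' @export
aco_config <- function(k, n_ants = 30L, evaporation_rate = 0.1,
                       deposit_scale = 1,
                       deposit_rule = c("iteration_best", "all_ants"),
                       max_iterations = 200L,
                       stall_limit = 30L, n_replications = 3L,
                       clamp_sens = TRUE, seed = 1L) {
  deposit_rule <- match.arg(deposit_rule)
  stopifnot_scalar_prob(evaporation_rate, "evaporation_rate", 0, 1,
                        open_lo = TRUE, open_hi = TRUE)
  if (deposit_scale <= 0) stop("`deposit_scale` must be positive", call. = FALSE)
  if (n_replications < 1) stop("`n_replications` must be >= 1", call. = FALSE)
  structure(
    list(k = as.integer(k), n_ants = as.integer(n_ants),
         evaporation_rate = evaporation_rate, deposit_scale = deposit_scale,
         deposit_rule = deposit_rule,
         max_iterations = as.integer(max_iterations),
         stall_limit = as.integer(stall_limit),
         n_replications = as.integer(n_replications),
         clamp_sens = isTRUE(clamp_sens), seed = as.integer(seed)),
    class = "aco_config"
  )
}

# One seeded ACO replication over a generic subset objective.
aco_run_once <- function(objective, n_items, config, seed) {
  with_seed(seed, {
    pheromone <- rep(1, n_items)
    best_idx <- NULL
    best_score <- -Inf
    trajectory <- numeric()
    evaluations <- 0L
    failed <- 0L
    stall <- 0L
    for (iter in seq_len(config$max_iterations)) {
      it_best <- NULL
      it_score <- -Inf
      ants <- vector("list", config$n_ants)
      for (ant in seq_len(config$n_ants)) {
        # sequential draws without replacement, renormalized each draw
        idx <- sample.int(n_items, config$k, prob = pheromone)
        s <- objective(idx)
        evaluations <- evaluations + 1L
        if (!is.finite(s)) {
          failed <- failed + 1L
          next
        }
        ants[[ant]] <- list(idx = idx, score = s)
        if (s > it_score) {
          it_score <- s
          it_best <- idx
        }
      }
      pheromone <- (1 - config$evaporation_rate) * pheromone
      if (config$deposit_rule == "all_ants") {
        for (a in ants) {
          if (is.null(a)) next
          pheromone[a$idx] <- pheromone[a$idx] +
            config$deposit_scale * max(a$score, 0) / config$n_ants
        }
      } else if (!is.null(it_best)) {
        pheromone[it_best] <- pheromone[it_best] +
          config$deposit_scale * max(it_score, 0)
      }
      if (it_score > best_score) {
        best_score <- it_score
        best_idx <- it_best
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      trajectory <- c(trajectory, best_score)
      if (stall >= config$stall_limit) break
    }
    list(best_idx = best_idx, best_score = best_score,
         trajectory = trajectory, evaluations = evaluations,
         failed = failed, pheromone = pheromone)
  })
}

#' Ant colony optimization item selection
#'
#' Samples fixed-size item subsets ("ants") with per-item probabilities
#' proportional to pheromone levels, scores each subset by the four-part
#' objective (model fit, omega reliability, mean-difficulty sensitivity,
#' covariate-correlation preservation; see [pheromone_components()]),
#' evaporates the pheromone, and deposits on the iteration-best subset's
#' items in proportion to its score, so that items of good subsets become
#' more likely to be drawn. The search is replicated `n_replications` times
#' with seeds `seed + r` and the replication with the highest objective is
#' returned.
#'
#' Subsets whose factor model does not converge score `-Inf` and are logged,
#' never fatal.
#'
#' @param data persons x items binary response matrix.
#' @param covariates persons x covariates numeric table (optional; without
#'   it the correlation-preservation pheromone is evaluated at 0 change).
#' @param config an [aco_config()].
#' @param corr optional precomputed [tetrachoric_matrix()] for `data`.
#' @param objective optional replacement objective `function(idx) -> score`
#'   (used for algorithm diagnostics; the default is the four-part
#'   pheromone objective).
#' @return A `selection_result`; `replication_scores` holds all
#'   `n_replications` best scores, `components` the winning subset's
#'   pheromone breakdown (when the default objective is used).
#' @export
aco_select <- function(data, covariates = NULL, config, corr = NULL,
                       objective = NULL) {
  stopifnot(inherits(config, "aco_config"))
  x <- as_response_matrix(data)
  m <- ncol(x)
  if (config$k < 3 || config$k >= m) {
    stop("need 3 <= k < number of items", call. = FALSE)
  }
  ev <- NULL
  if (is.null(objective)) {
    ev <- make_subset_evaluator(x, covariates, corr = corr,
                                clamp_sens = config$clamp_sens)
    objective <- function(idx) ev$evaluate(idx)$total
  }
  seeds <- config$seed + seq_len(config$n_replications)
  runs <- lapply(seeds, function(s) aco_run_once(objective, m, config, s))
  scores <- vapply(runs, `[[`, numeric(1), "best_score")
  winner <- which.max(scores)
  best <- runs[[winner]]
  new_selection_result(
    method = "ACO",
    best_subset = best$best_idx,
    item_ids = colnames(x),
    best_score = best$best_score,
    trajectory = best$trajectory,
    seeds = seeds,
    evaluations = sum(vapply(runs, `[[`, integer(1), "evaluations")),
    config = config,
    replication_scores = scores,
    failed_evaluations = sum(vapply(runs, `[[`, integer(1), "failed")),
    pheromone = best$pheromone,
    components = if (!is.null(ev)) ev$evaluate(best$best_idx)$components
  )
}
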