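#' Configuration for the genetic algorithm
#'
#' Hyperparameters of the steady-state genetic search over item-inclusion
#' masks. Defaults: population 100, uniform crossover at rate .9,
#' per-position mutation at rate 1/L (set when the pool size is known),
#' replacement of the worst population member by a better offspring, and
#' one elite member that is never displaced.
#'
#' @param item_cost_I fixed cost per retained item in the cost function
#'   `I * k + (1 - R^2)`.
#' @param population_size number of candidate masks kept (>= 4).
#' @param crossover_rate probability that an offspring is produced by
#'   uniform crossover rather than cloning.
#' @param mutation_rate per-position flip probability; `NULL` means 1/L.
#' @param max_generations offspring evaluations before stopping.
#' @param stall_limit generations without improvement before stopping.
#' @param elitism_count number of top members protected from replacement.
#' @param fixed_k optional target length enforced by random add/drop repair.
#' @param seed integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(item_cost_I = 0.05, population_size = 100L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      max_generations = 1000L, stall_limit = 200L,
                      elitism_count = 1L, fixed_k = NULL, seed = 1L) {
  if (item_cost_I < 0) stop("`item_cost_I` must be >= 0", call. = FALSE)
  if (population_size < 4) stop("`population_size` must be >= 4", call. = FALSE)
  stopifnot_scalar_prob(crossover_rate, "crossover_rate", 0, 1)
  if (!is.null(mutation_rate)) {
    stopifnot_scalar_prob(mutation_rate, "mutation_rate", 0, 1)
  }
  structure(
    list(item_cost_I = item_cost_I,
         population_size = as.integer(population_size),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         max_generations = as.integer(max_generations),
         stall_limit = as.integer(stall_limit),
         elitism_count = as.integer(elitism_count),
         fixed_k = if (!is.null(fixed_k)) as.integer(fixed_k),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

# Uniform crossover of two inclusion masks; with probability
# 1 - crossover_rate the offspring is a clone of the first parent.
ga_crossover <- function(p1, p2, crossover_rate) {
  if (stats::runif(1) >= crossover_rate) return(p1)
  take1 <- stats::runif(length(p1)) < 0.5
  ifelse(take1, p1, p2)
}

# Flip each position independently with probability `mutation_rate`.
ga_mutate <- function(mask, mutation_rate) {
  flip <- stats::runif(length(mask)) < mutation_rate
  xor(mask, flip)
}

# Enforce the size constraints: exactly fixed_k when set, at least 1 item
# otherwise, by random drops/additions.
ga_repair <- function(mask, fixed_k) {
  size <- sum(mask)
  if (is.null(fixed_k)) {
    if (size == 0L) mask[sample.int(length(mask), 1L)] <- TRUE
    return(mask)
  }
  while (sum(mask) > fixed_k) {
    inc <- which(mask)
    mask[inc[sample.int(length(inc), 1L)]] <- FALSE
  }
  while (sum(mask) < fixed_k) {
    exc <- which(!mask)
    mask[exc[sample.int(length(exc), 1L)]] <- TRUE
  }
  mask
}

#' Genetic-algorithm item selection
#'
#' Evolves item-inclusion masks to minimize the cost
#' `I * k + (1 - R^2)` (see [ga_cost()]), where `R^2` is the variance of the
#' full-pool unit-weighted total score explained by an ordinary
#' least-squares regression (with intercept) on the candidate's item
#' scores. Parents are chosen by rank-proportional selection, offspring are
#' produced by uniform crossover and per-position mutation, repaired to
#' `fixed_k` items when that is set, and replace the worst non-elite
#' population member when strictly better (steady-state replacement).
#'
#' @param data persons x items binary response matrix.
#' @param config a [ga_config()].
#' @return A `selection_result`; `best_score` is the negative cost, and
#'   `r_squared`/`cost` report the winning subset's components.
#' @export
ga_select <- function(data, config) {
  stopifnot(inherits(config, "ga_config"))
  x <- as_response_matrix(data)
  m <- ncol(x)
  if (!is.null(config$fixed_k) && (config$fixed_k < 1 || config$fixed_k > m)) {
    stop("`fixed_k` must lie in [1, number of items]", call. = FALSE)
  }
  mut <- config$mutation_rate %||% (1 / m)
  y <- rowSums(x)
  tss <- sum((y - mean(y))^2)
  cache <- new.env(parent = emptyenv())
  r_squared <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- stats::lm.fit(cbind(1, x[, idx, drop = FALSE]), y)
    r2 <- if (tss > 0) max(0, min(1, 1 - sum(fit$residuals^2) / tss)) else 1
    cache[[key]] <- r2
    r2
  }
  fitness <- function(mask) {
    idx <- which(mask)
    -ga_cost(config$item_cost_I, length(idx), r_squared(idx))
  }

  out <- with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      mask <- if (is.null(config$fixed_k)) {
        stats::runif(m) < 0.5
      } else {
        seq_len(m) %in% sample.int(m, config$fixed_k)
      }
      ga_repair(mask, config$fixed_k)
    })
    fit <- vapply(pop, fitness, numeric(1))
    evaluations <- length(pop)
    best <- max(fit)
    trajectory <- numeric()
    stall <- 0L
    for (gen in seq_len(config$max_generations)) {
      # rank-proportional parent selection (higher fitness, higher rank)
      pr <- rank(fit, ties.method = "first")
      parents <- sample.int(length(pop), 2L, prob = pr)
      child <- ga_crossover(pop[[parents[1]]], pop[[parents[2]]],
                            config$crossover_rate)
      child <- ga_mutate(child, mut)
      child <- ga_repair(child, config$fixed_k)
      f <- fitness(child)
      evaluations <- evaluations + 1L
      ord <- order(fit)
      protected <- ord[length(ord) - seq_len(config$elitism_count) + 1L]
      worst <- setdiff(ord, protected)[1L]
      if (f > fit[worst]) {
        pop[[worst]] <- child
        fit[worst] <- f
      }
      if (max(fit) > best) {
        best <- max(fit)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      trajectory <- c(trajectory, best)
      if (stall >= config$stall_limit) break
    }
    winner <- which.max(fit)
    list(mask = pop[[winner]], score = fit[winner],
         trajectory = trajectory, evaluations = evaluations)
  })
  idx <- which(out$mask)
  r2 <- r_squared(idx)
  new_selection_result(
    method = "GA",
    best_subset = idx,
    item_ids = colnames(x),
    best_score = out$score,
    trajectory = out$trajectory,
    seeds = config$seed,
    evaluations = out$evaluations,
    config = config,
    r_squared = r2,
    cost = ga_cost(config$item_cost_I, length(idx), r2)
  )
}

#' Find the item cost that yields a target scale length
#'
#' The per-item cost `I` controls the brevity/comprehensiveness trade-off of
#' the genetic algorithm; this searches `I` by bisection until the
#' unconstrained GA's best solution retains exactly `target_k` items.
#'
#' @param data persons x items binary response matrix.
#' @param target_k desired short-form length (>= 3).
#' @param config a [ga_config()] used as template (`item_cost_I` and
#'   `fixed_k` are overridden).
#' @param bracket lower/upper bounds on `I` for the bisection.
#' @param max_steps bisection budget.
#' @return A list with `item_cost_I`, the corresponding `result`
#'   (`selection_result`), `achieved_k`, and `target_met` (FALSE when the
#'   budget ran out and the nearest-k solution is returned, with a warning).
#' @export
tune_item_cost <- function(data, target_k, config = ga_config(),
                           bracket = c(1e-5, 0.5), max_steps = 20L) {
  if (target_k < 3) stop("`target_k` must be >= 3", call. = FALSE)
  x <- as_response_matrix(data)
  run <- function(I) {
    cfg <- config
    cfg$item_cost_I <- I
    cfg$fixed_k <- NULL
    ga_select(x, cfg)
  }
  lo <- bracket[1]
  hi <- bracket[2]
  best <- NULL
  best_I <- NA_real_
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    res <- run(mid)
    if (is.null(best) || abs(res$k - target_k) < abs(best$k - target_k)) {
      best <- res
      best_I <- mid
    }
    if (res$k == target_k) {
      return(list(item_cost_I = mid, result = res, achieved_k = res$k,
                  target_met = TRUE))
    }
    if (res$k > target_k) lo <- mid else hi <- mid # larger I -> shorter scale
  }
  warning(sprintf(
    "no item cost in [%g, %g] gave exactly %d items within %d steps; nearest is %d items",
    bracket[1], bracket[2], target_k, max_steps, best$k
  ), call. = FALSE)
  list(item_cost_I = best_I, result = best, achieved_k = best$k,
       target_met = FALSE)
}
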