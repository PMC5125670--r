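test_that("stepwise deletion removes items in ascending loading order", {
  cfg <- simulation_config(4000, loadings = c(0.2, 0.5, 0.7, 0.9),
                           difficulties = rep(0.6, 4), guessing = 0, seed = 1)
  s <- simulate_responses(cfg)
  res <- scofa_select(s$responses, k = 2)
  expect_identical(res$best_items, c("item03", "item04"))
  expect_identical(res$removal_order, c(1L, 2L))
  # single-step case: drops exactly the argmin-loading item of the full fit
  corr <- tetrachoric_matrix(s$responses)
  full <- fit_one_factor(corr)
  res1 <- scofa_select(s$responses, k = 3, corr = corr)
  expect_identical(res1$removal_order, unname(which.min(coef(full))))
  expect_identical(res1$evaluations, 2L)
})

test_that("loading ties are broken by the lower item index", {
  # a perfectly exchangeable implied matrix makes all loadings equal
  R <- implied_corr(rep(0.6, 5))
  corr <- structure(list(values = R, item_ids = paste0("i", 1:5),
                         n_persons = 500L), class = "corr_matrix")
  x <- matrix(rep(c(0L, 1L), 50), ncol = 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  res <- scofa_select(x, k = 3, corr = corr)
  expect_identical(res$removal_order, c(1L, 2L))
})

test_that("ant colony recovers a planted optimum over C(6,3) subsets", {
  x <- matrix(rbinom(600, 1, 0.5), ncol = 6,
              dimnames = list(NULL, paste0("i", 1:6)))
  planted <- c(2L, 4L, 5L)
  obj <- function(idx) if (identical(sort(idx), planted)) 4 else 0
  hits <- sum(vapply(1:100, function(i) {
    res <- aco_select(x, config = aco_config(
      k = 3, n_ants = 10, max_iterations = 40, stall_limit = 40,
      n_replications = 1, seed = 7 * i
    ), objective = obj)
    identical(res$best_subset, planted)
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("a flat objective leaves the balanced-deposit pheromone near uniform", {
  # the all-ant (ant-system) rule reinforces every sampled subset equally
  # under a constant objective, so no item can pull ahead; the
  # winner-take-all iteration-best rule does not have this property
  x <- matrix(rbinom(800, 1, 0.5), ncol = 8,
              dimnames = list(NULL, paste0("i", 1:8)))
  res <- aco_select(x, config = aco_config(
    k = 3, n_ants = 200, max_iterations = 50, stall_limit = 50,
    n_replications = 1, evaporation_rate = 0.1, seed = 12,
    deposit_rule = "all_ants"
  ), objective = function(idx) 1)
  expect_lt(max(res$pheromone) / min(res$pheromone), 1.5)
})

test_that("the reported ant-colony run is the best of its replications", {
  s <- fixture_small_pool()
  res <- aco_select(s$responses, s$covariates, aco_config(
    k = 4, n_ants = 8, max_iterations = 15, stall_limit = 15,
    n_replications = 3, seed = 5
  ), corr = s$corr)
  expect_length(res$replication_scores, 3)
  expect_identical(res$seeds, 5L + 1:3)
  expect_equal(res$best_score, max(res$replication_scores))
})

test_that("best-so-far trajectories never decrease and runs are deterministic", {
  s <- fixture_small_pool()
  cfg <- aco_config(k = 4, n_ants = 8, max_iterations = 15, stall_limit = 15,
                    n_replications = 2, seed = 3)
  a1 <- aco_select(s$responses, s$covariates, cfg, corr = s$corr)
  a2 <- aco_select(s$responses, s$covariates, cfg, corr = s$corr)
  expect_identical(a1$best_subset, a2$best_subset)
  expect_identical(a1$trajectory, a2$trajectory)
  expect_true(all(diff(a1$trajectory[is.finite(a1$trajectory)]) >= 0))
  gcfg <- ga_config(fixed_k = 4, max_generations = 300, stall_limit = 100,
                    seed = 3)
  g1 <- ga_select(s$responses, gcfg)
  g2 <- ga_select(s$responses, gcfg)
  expect_identical(g1$best_subset, g2$best_subset)
  expect_true(all(diff(g1$trajectory) >= 0))
  expect_gt(g1$evaluations, 0L)
})

test_that("crossover of identical parents without mutation is the identity", {
  p <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  set.seed(4)
  for (i in 1:10) {
    child <- scaleshort:::ga_crossover(p, p, crossover_rate = 1)
    expect_identical(scaleshort:::ga_mutate(child, 0), p)
  }
})

test_that("repair enforces the size constraints", {
  set.seed(6)
  empty <- rep(FALSE, 6)
  expect_equal(sum(scaleshort:::ga_repair(empty, NULL)), 1)
  expect_equal(sum(scaleshort:::ga_repair(rep(TRUE, 6), 3L)), 3)
  expect_equal(sum(scaleshort:::ga_repair(empty, 4L)), 4)
})

test_that("the genetic algorithm matches the exhaustive cost minimum", {
  s <- fixture_small_pool()
  y <- rowSums(s$responses)
  tss <- sum((y - mean(y))^2)
  I <- 0.01
  subs <- combn(10, 4)
  costs <- apply(subs, 2, function(ix) {
    fit <- lm.fit(cbind(1, s$responses[, ix, drop = FALSE]), y)
    I * 4 + sum(fit$residuals^2) / tss
  })
  cmin <- min(costs)
  hits <- sum(vapply(1:25, function(i) {
    r <- ga_select(s$responses, ga_config(
      item_cost_I = I, fixed_k = 4, max_generations = 600,
      stall_limit = 200, seed = 2000 + i
    ))
    (-r$best_score) <= cmin * 1.01
  }, logical(1)))
  expect_gte(hits, 23) # >= 90% of seeded runs
})

test_that("a vanishing item cost keeps the whole pool", {
  # small noisy pool in which every item carries unique signal
  cfg <- simulation_config(800, loadings = seq(0.35, 0.75, length.out = 6),
                           difficulties = seq(0.4, 0.8, length.out = 6),
                           guessing = 0, seed = 14)
  s <- simulate_responses(cfg)
  r <- ga_select(s$responses, ga_config(item_cost_I = 0,
                                        max_generations = 600,
                                        stall_limit = 300, seed = 4))
  expect_identical(r$k, 6L)
})

test_that("larger item costs never buy longer scales", {
  s <- fixture_small_pool()
  ks <- vapply(c(0.001, 0.005, 0.02, 0.08), function(I) {
    ga_select(s$responses, ga_config(item_cost_I = I, max_generations = 600,
                                     stall_limit = 200, seed = 10))$k
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("bisection on the item cost reaches the target length", {
  s <- fixture_small_pool()
  tuned <- tune_item_cost(s$responses, target_k = 5,
                          config = ga_config(max_generations = 500,
                                             stall_limit = 150, seed = 21))
  expect_true(tuned$target_met)
  expect_identical(tuned$achieved_k, 5L)
  expect_identical(tuned$result$k, 5L)
})
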