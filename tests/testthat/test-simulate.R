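test_that("identical seeds give bit-identical data; different seeds differ", {
  cfg <- simulation_config(200, loadings = rep(0.6, 5),
                           difficulties = rep(0.6, 5),
                           covariates = c(z = 0.4), seed = 8)
  s1 <- simulate_responses(cfg)
  s2 <- simulate_responses(cfg)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$covariates, s2$covariates)
  cfg2 <- cfg
  cfg2$seed <- 9L
  expect_false(identical(simulate_responses(cfg2)$responses, s1$responses))
})

test_that("a guessing floor of 1 makes every response correct", {
  cfg <- simulation_config(60, loadings = rep(0.5, 3),
                           difficulties = c(0.5, 0.6, 0.7),
                           guessing = 1, seed = 3)
  s <- simulate_responses(cfg)
  expect_true(all(s$responses == 1L))
})

test_that("thresholds match the closed-form probit calibration", {
  lam <- c(0.3, 0.55, 0.75)
  p <- c(0.4, 0.625, 0.85)
  c0 <- 0.25
  cfg <- simulation_config(50, loadings = lam, difficulties = p,
                           guessing = c0, seed = 2)
  s <- simulate_responses(cfg)
  a <- lam / sqrt(1 - lam^2)
  tau_closed <- -sqrt(1 + a^2) * qnorm((p - c0) / (1 - c0))
  expect_equal(unname(s$truth$thresholds), tau_closed, tolerance = 1e-5)
})

test_that("population marginals hit their targets at large n", {
  cfg <- simulation_config(20000,
                           loadings = c(0.5, 0.6, 0.7),
                           difficulties = c(0.625, 0.4, 0.9),
                           guessing = 0.25, seed = 7)
  s <- simulate_responses(cfg)
  expect_true(all(abs(colMeans(s$responses) - c(0.625, 0.4, 0.9)) < 0.02))
})

test_that("covariates correlate with the trait as declared", {
  cfg <- simulation_config(10000, loadings = rep(0.6, 3),
                           difficulties = rep(0.6, 3),
                           covariates = c(a = 0.5, b = -0.3), seed = 5)
  s <- simulate_responses(cfg)
  expect_lt(abs(cor(s$truth$latent_traits, s$covariates$a) - 0.5), 0.03)
  expect_lt(abs(cor(s$truth$latent_traits, s$covariates$b) + 0.3), 0.03)
  # conditional independence given the trait: cor(a, b) ~ rho_a * rho_b
  expect_lt(abs(cor(s$covariates$a, s$covariates$b) + 0.15), 0.04)
})

test_that("infeasible targets and structures are rejected with context", {
  expect_error(
    simulate_responses(simulation_config(
      50, loadings = rep(0.5, 3), difficulties = c(0.6, 0.2, 0.7),
      guessing = 0.25, seed = 1
    )),
    "item02.*guessing floor"
  )
  bad_cor <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3, 3)
  expect_error(
    simulation_config(50, loadings = rep(0.5, 3), difficulties = rep(0.6, 3),
                      covariates = c(a = 0.1, b = 0.1, c = 0.1),
                      covariate_cor = bad_cor, seed = 1),
    "positive definite"
  )
  expect_error(simulation_config(50, loadings = rep(0.5, 2),
                                 difficulties = rep(0.6, 2)),
               "at least 3 items")
})

test_that("the 89-item pool preset matches its documented shape", {
  pool <- make_ppvt_like_pool(11)
  expect_identical(pool$n_items, 89L)
  expect_equal(range(pool$loadings), c(-0.03, 0.81))
  expect_equal(mean(pool$loadings), 0.41, tolerance = 0.01)
  expect_equal(mean(pool$difficulties), 0.64, tolerance = 0.01)
  expect_true(all(pool$difficulties > 0.25)) # above the guessing floor
  expect_equal(pool$guessing, 0.25)
  expect_gt(cor(pool$loadings, pool$difficulties, method = "spearman"), 0.5)
  expect_identical(make_ppvt_like_pool(11)$difficulties, pool$difficulties)
  expect_false(identical(make_ppvt_like_pool(12)$loadings, pool$loadings))
})

test_that("truth records round-trip through JSON", {
  s <- fixture_small_pool()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_record(s$truth, path)
  back <- read_truth_record(path)
  expect_equal(back$loadings, s$truth$loadings)
  expect_equal(back$difficulties, s$truth$difficulties)
  expect_equal(back$thresholds, s$truth$thresholds)
  expect_equal(back$guessing, s$truth$guessing)
  expect_equal(back$covariate_trait_corrs, s$truth$covariate_trait_corrs)
})
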