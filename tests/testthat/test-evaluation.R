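test_that("the full pool evaluates as its own reference", {
  s <- fixture_small_pool()
  ev <- evaluate_short_form(s$responses, s$covariates, 1:10, corr = s$corr)
  expect_equal(unname(ev$delta_r), rep(0, 3))
  expect_equal(ev$max_abs_delta_r, 0)
  expect_equal(ev$k, 10)
  expect_equal(ev$mean_difficulty, mean(colMeans(s$responses)))
})

test_that("difficulty and sensitivity line up on a calibrated fixture", {
  cfg <- simulation_config(20000, loadings = rep(0.55, 6),
                           difficulties = rep(0.625, 6),
                           guessing = 0.25, seed = 19)
  s <- simulate_responses(cfg)
  ev <- evaluate_short_form(s$responses, NULL, 1:3)
  expect_lt(abs(ev$mean_difficulty - 0.625), 0.02)
  expect_gt(ev$phi$phi_sens, 0.99)
})

test_that("exchangeable subsets give near-identical omega", {
  cfg <- simulation_config(6000, loadings = rep(0.6, 8),
                           difficulties = rep(0.6, 8),
                           guessing = 0, seed = 23)
  s <- simulate_responses(cfg)
  corr <- tetrachoric_matrix(s$responses)
  e1 <- evaluate_short_form(s$responses, NULL, c(1, 3, 5, 7), corr = corr)
  e2 <- evaluate_short_form(s$responses, NULL, c(2, 4, 6, 8), corr = corr)
  expect_equal(e1$omega, e2$omega, tolerance = 0.05)
})

test_that("delta-r summaries are invariant to covariate ordering", {
  s <- fixture_small_pool()
  e1 <- evaluate_short_form(s$responses, s$covariates, 2:6, corr = s$corr)
  e2 <- evaluate_short_form(s$responses, s$covariates[, c(3, 1, 2)], 2:6,
                            corr = s$corr)
  expect_equal(e1$max_abs_delta_r, e2$max_abs_delta_r)
  expect_equal(e1$delta_r[names(e2$delta_r)], e2$delta_r)
})

test_that("comparison tables have one row per form plus the reference", {
  s <- fixture_small_pool()
  evs <- list(
    evaluate_short_form(s$responses, s$covariates, 1:5, "A", corr = s$corr),
    evaluate_short_form(s$responses, s$covariates, 3:8, "B", corr = s$corr)
  )
  tab <- compare_methods(evs, s$responses, s$covariates, corr = s$corr)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$method, c("A", "B", "long form"))
  expect_equal(tab$max_abs_delta_r[3], 0)
  # byte-identical regeneration
  tab2 <- compare_methods(evs, s$responses, s$covariates, corr = s$corr)
  expect_identical(tab, tab2)
})

test_that("good model fit is flagged at CFI >= .95 and RMSEA <= .08", {
  s <- fixture_small_pool()
  ev <- evaluate_short_form(s$responses, s$covariates, 1:5, corr = s$corr)
  make_row <- function(cfi, rmsea) {
    e <- ev
    e$cfa$cfi <- cfi
    e$cfa$rmsea <- rmsea
    e
  }
  tab <- compare_methods(list(make_row(0.96, 0.02), make_row(0.94, 0.02),
                              make_row(0.96, 0.10)),
                         s$responses, s$covariates, corr = s$corr)
  expect_identical(tab$good_fit[1:3], c(TRUE, FALSE, FALSE))
})

test_that("mismatched pools and bad subsets are rejected", {
  s <- fixture_small_pool()
  ev <- evaluate_short_form(s$responses, s$covariates, 1:5, corr = s$corr)
  expect_error(compare_methods(list(ev), s$responses[, 1:8]),
               "different item pool")
  expect_error(evaluate_short_form(s$responses, s$covariates, c(1, 99)),
               "out of range")
  expect_error(evaluate_short_form(s$responses, s$covariates, c("item01", "nope")),
               "unknown item")
})
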