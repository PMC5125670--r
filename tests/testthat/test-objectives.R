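test_that("each logistic transform sits exactly at 0.5 at its cutoff", {
  expect_equal(phi_cfi(0.95), 0.5)
  expect_equal(phi_rmsea(0.05), 0.5)
  expect_equal(phi_rel(0.90), 0.5)
  expect_equal(phi_cor(0.03), 0.5)
  expect_equal(phi_sens(0.625), 1.0)
})

test_that("transforms reproduce their closed-form values away from the cutoffs", {
  expect_equal(phi_cfi(1.0), 1 / (1 + exp(-5)))
  expect_equal(phi_cfi(0.90), 1 / (1 + exp(5)))
  expect_equal(phi_rmsea(0), 1 - 1 / (1 + exp(5)))
  expect_equal(phi_rmsea(0.10), 1 - 1 / (1 + exp(-5)))
  expect_equal(phi_rel(1.0), 1 / (1 + exp(-1)))
  expect_equal(phi_rel(0), 1 / (1 + exp(9)))
  expect_equal(phi_cor(0), 1 - 1 / (1 + exp(3)))
  expect_equal(phi_cor(0.10), 1 - 1 / (1 + exp(-7)))
  expect_equal(phi_sens(0.925), 0.55)
  expect_equal(phi_sens(0.125, clamp = FALSE), -0.25)
  expect_equal(phi_sens(0.125, clamp = TRUE), 0)
  expect_equal(phi_fit(1 / (1 + exp(-5)), 1 / (1 + exp(5))), 0.5)
  expect_equal(phi_fit(0.5, 0.5), 0.5)
})

test_that("transforms are monotone on dense grids and sens is symmetric", {
  g <- seq(0, 1, length.out = 1000)
  expect_true(all(diff(phi_cfi(g)) > 0))
  expect_true(all(diff(phi_rel(g)) > 0))
  expect_true(all(diff(phi_rmsea(g)) < 0))
  expect_true(all(diff(phi_cor(g)) < 0))
  d <- seq(0, 0.375, length.out = 200)
  expect_equal(phi_sens(0.625 + d, clamp = FALSE),
               phi_sens(0.625 - d, clamp = FALSE))
})

test_that("out-of-range fit indices and difficulties are rejected", {
  expect_error(phi_cfi(1.2), "\\[0, 1\\]")
  expect_error(phi_rmsea(-0.01), "nonnegative")
  expect_error(phi_rel(-0.1), "\\[0, 1\\]")
  expect_error(phi_sens(1.5), "\\[0, 1\\]")
  expect_error(phi_cor(-0.2), "\\[0, 2\\]")
})

test_that("component records sum the four criteria", {
  pc <- pheromone_components(cfi = 0.95, rmsea = 0.05, omega = 0.625 * 1.44,
                             mean_difficulty = 0.625, max_abs_diff = 0.03)
  expect_equal(pc$phi_fit, 0.5)
  expect_equal(pc$total, total_objective(pc))
  # all four criteria at their cutoffs: 0.5 + 0.5 + 1 + 0.5
  pc2 <- pheromone_components(0.95, 0.05, 0.90, 0.625, 0.03)
  expect_equal(pc2$total, 2.5)
  # clamped sensitivity at 0 with the others at 0.5
  pc3 <- pheromone_components(0.95, 0.05, 0.90, 0.125, 0.03)
  expect_equal(pc3$total, 1.5)
  # supremum: every component at its best is bounded by 4
  pc4 <- pheromone_components(1, 0, 1, 0.625, 0)
  expect_lt(pc4$total, 4)
})

test_that("the GA cost trades brevity against explained variance", {
  expect_equal(ga_cost(0, k = 37, r_squared = 1), 0)
  expect_equal(ga_cost(0.05, k = 20, r_squared = 0.95), 1.05)
  # shorter wins when the variance loss is small relative to the item cost
  expect_lt(ga_cost(0.05, 15, 0.95), ga_cost(0.05, 20, 0.97))
  # strictly increasing in k at fixed R^2 whenever I > 0
  ks <- 1:60
  expect_true(all(diff(ga_cost(0.02, ks, 0.9)) > 0))
  expect_error(ga_cost(-1, 5, 0.5), ">= 0")
  expect_error(ga_cost(0.1, 5, 1.2), "\\[0, 1\\]")
})
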