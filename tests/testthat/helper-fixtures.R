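# Shared fixtures, built once per test run.

# Small calibrated pool with covariates: 10 items, mixed loadings and
# difficulties, guessing floor .25.
fixture_small_pool <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- simulation_config(
        n_persons = 1200,
        loadings = seq(0.25, 0.8, length.out = 10),
        difficulties = seq(0.35, 0.9, length.out = 10),
        guessing = 0.25,
        covariates = c(a = 0.55, b = 0.30, c = 0.05),
        seed = 77
      )
      s <- simulate_responses(cfg)
      s$corr <- tetrachoric_matrix(s$responses)
      s$config <- cfg
      memo <<- s
    }
    memo
  }
})

# Model-implied one-factor correlation matrix for given loadings.
implied_corr <- function(lambda) {
  R <- tcrossprod(lambda)
  diag(R) <- 1
  R
}

# Independent bivariate-normal CDF using one-dimensional adaptive
# quadrature (a different route than the package's angular reduction).
pbvnorm_ref <- function(h, k, r) {
  f <- function(x) pnorm((k - r * x) / sqrt(1 - r^2)) * dnorm(x)
  integrate(f, -Inf, h, rel.tol = 1e-12)$value
}

# Brute-force tetrachoric oracle: maximize the full 3-parameter
# bivariate-normal likelihood (r, tau1, tau2) by coarse grid search plus
# Nelder-Mead refinement, with the reference CDF above.
tetrachoric_oracle <- function(n11, n10, n01, n00) {
  counts <- c(n11, n10, n01, n00)
  ll <- function(par) {
    r <- par[1]; t1 <- par[2]; t2 <- par[3]
    if (abs(r) >= 0.999) return(1e10)
    p11 <- 1 - pnorm(t1) - pnorm(t2) + pbvnorm_ref(t1, t2, r)
    p10 <- (1 - pnorm(t1)) - p11
    p01 <- (1 - pnorm(t2)) - p11
    p00 <- 1 - p11 - p10 - p01
    p <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(counts * log(p))
  }
  grid <- expand.grid(r = seq(-0.95, 0.95, by = 0.05),
                      t1 = seq(-2, 2, by = 0.25),
                      t2 = seq(-2, 2, by = 0.25))
  vals <- apply(grid, 1, ll)
  start <- as.numeric(grid[which.min(vals), ])
  optim(start, ll, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 2000))$par
}

# Exhaustive minimizer of the one-factor ULS discrepancy by coarse grid
# over the loadings followed by Nelder-Mead refinement.
uls_grid_oracle <- function(R, step = 0.1) {
  m <- ncol(R)
  up <- upper.tri(R)
  f <- function(l) sum((R - tcrossprod(l))[up]^2)
  pts <- seq(-0.9, 0.9, by = step)
  grid <- as.matrix(do.call(expand.grid, rep(list(pts), m)))
  vals <- apply(grid, 1, f)
  start <- grid[which.min(vals), ]
  optim(start, f, method = "Nelder-Mead",
        control = list(reltol = 1e-14, maxit = 5000))$value
}
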