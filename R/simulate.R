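# Seeded simulator of guessing-affected dichotomous item responses with
# known loadings, difficulties, and trait-correlated covariates.

# Gauss-Hermite quadrature for E[g(theta)], theta ~ N(0,1): Golub-Welsch on
# the Hermite Jacobi matrix, transformed to the probabilists' scale.
gauss_hermite_normal <- local({
  cache <- list()
  function(n = 61L) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      i <- seq_len(n - 1)
      b <- sqrt(i / 2)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- b
      J[cbind(i + 1, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      cache[[key]] <<- list(nodes = e$values * sqrt(2),
                            weights = e$vectors[1, ]^2)
    }
    cache[[key]]
  }
})

item_response_curve <- function(theta, a, tau, guessing, link) {
  kernel <- switch(link,
    probit = stats::pnorm(a * theta - tau),
    logit = stats::plogis(1.702 * (a * theta - tau))
  )
  guessing + (1 - guessing) * kernel
}

# Population proportion correct for one item, by quadrature over the trait.
marginal_correct <- function(a, tau, guessing, link, gh = gauss_hermite_normal()) {
  sum(gh$weights * item_response_curve(gh$nodes, a, tau, guessing, link))
}

# Root-find the threshold tau so the population marginal hits `target`
# (tolerance 1e-6 on the marginal).
calibrate_threshold <- function(a, target, guessing, link, item_name) {
  if (target <= guessing) {
    stop(sprintf(
      "item '%s': target difficulty %.3f is not attainable with guessing floor %.2f",
      item_name, target, guessing
    ), call. = FALSE)
  }
  gh <- gauss_hermite_normal()
  f <- function(tau) marginal_correct(a, tau, guessing, link, gh) - target
  sol <- stats::uniroot(f, interval = c(-40, 40), tol = 1e-9)
  if (abs(f(sol$root)) > 1e-6) {
    stop(sprintf("item '%s': threshold calibration did not converge", item_name),
         call. = FALSE)
  }
  sol$root
}

#' Configure a synthetic item-response study
#'
#' Fixes the generating model for [simulate_responses()]: a one-factor
#' normal-trait model with standardized loadings `lambda_i`, a lower
#' asymptote `guessing` (the probability of a correct answer by chance on a
#' multiple-choice item; .25 for four response alternatives), and per-item
#' thresholds calibrated numerically so each item's population proportion
#' correct equals its target difficulty. Covariates are generated jointly
#' multivariate-normal with the trait at the declared correlations and are
#' mutually independent given the trait unless `covariate_cor` supplies
#' pairwise correlations.
#'
#' When `loading_difficulty_corr` is set, the difficulty targets are
#' rank-reordered against the loadings (Iman-Conover style, using the config
#' seed) to impose the requested rank correlation between loadings and
#' easiness -- the confound under which stepwise selection by loading drifts
#' toward easy, redundant items.
#'
#' @param n_persons number of simulated respondents.
#' @param loadings per-item standardized loadings, each in (-1, 1); length
#'   defines the number of items (at least 3).
#' @param difficulties per-item target proportions correct, each in (0, 1)
#'   and above the guessing floor.
#' @param guessing lower asymptote in \[0, 1\]; the degenerate value 1 makes
#'   every response correct.
#' @param covariates named numeric vector of covariate-trait correlations,
#'   each in (-1, 1); may be empty.
#' @param covariate_cor optional symmetric matrix of pairwise covariate
#'   correlations (defaults to the conditional-independence structure).
#' @param loading_difficulty_corr optional target rank correlation between
#'   loadings and difficulty targets.
#' @param link item response function: `"probit"` (default) or `"logit"`.
#' @param seed integer seed; identical configs give bit-identical data.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_persons, loadings, difficulties,
                              guessing = 0.25, covariates = numeric(),
                              covariate_cor = NULL,
                              loading_difficulty_corr = NULL,
                              link = c("probit", "logit"), seed = 1L) {
  link <- match.arg(link)
  n_items <- length(loadings)
  if (n_items < 3L) stop("need at least 3 items", call. = FALSE)
  if (length(difficulties) != n_items) {
    stop("`difficulties` must match `loadings` in length", call. = FALSE)
  }
  if (any(abs(loadings) >= 1)) stop("loadings must lie in (-1, 1)", call. = FALSE)
  if (any(difficulties <= 0 | difficulties >= 1)) {
    stop("difficulties must lie in (0, 1)", call. = FALSE)
  }
  stopifnot_scalar_prob(guessing, "guessing", 0, 1)
  if (length(covariates) && is.null(names(covariates))) {
    names(covariates) <- paste0("cov", seq_along(covariates))
  }
  if (any(abs(covariates) >= 1)) {
    stop("covariate-trait correlations must lie in (-1, 1)", call. = FALSE)
  }
  q <- length(covariates)
  # joint correlation matrix of (trait, covariates)
  S <- diag(q + 1)
  if (q) {
    S[1, -1] <- S[-1, 1] <- covariates
    if (is.null(covariate_cor)) {
      C <- tcrossprod(covariates) # conditional independence given the trait
      diag(C) <- 1
      S[-1, -1] <- C
    } else {
      C <- as.matrix(covariate_cor)
      if (!isTRUE(all.equal(dim(C), c(q, q))) || max(abs(C - t(C))) > 1e-10) {
        stop("`covariate_cor` must be a symmetric q x q matrix", call. = FALSE)
      }
      S[-1, -1] <- C
      diag(S) <- 1
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("declared covariate structure is not positive definite", call. = FALSE)
    }
  }
  if (!is.null(loading_difficulty_corr)) {
    stopifnot_scalar_prob(loading_difficulty_corr, "loading_difficulty_corr",
                          -1, 1, open_lo = TRUE, open_hi = TRUE)
    difficulties <- with_seed(seed + 211L, impose_rank_corr(
      loadings, difficulties, loading_difficulty_corr
    ))
  }
  if (is.null(names(loadings))) {
    names(loadings) <- sprintf("item%02d", seq_len(n_items))
  }
  names(difficulties) <- names(loadings)
  structure(
    list(
      n_persons = as.integer(n_persons), n_items = n_items,
      loadings = loadings, difficulties = difficulties,
      guessing = guessing, covariates = covariates,
      joint_cor = S, loading_difficulty_corr = loading_difficulty_corr,
      link = link, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Iman-Conover-style reordering: permute `values` so that its rank
# correlation with `anchor` is close to `target_r`.
impose_rank_corr <- function(anchor, values, target_r) {
  n <- length(anchor)
  z <- stats::qnorm(rank(anchor, ties.method = "first") / (n + 1))
  y <- target_r * z + sqrt(1 - target_r^2) * stats::rnorm(n)
  sort(values)[rank(y, ties.method = "first")]
}

#' Simulate responses, covariates, and ground truth
#'
#' Draws the trait and covariates jointly multivariate-normal, calibrates
#' each item's threshold so its population proportion correct equals the
#' target difficulty, and samples Bernoulli responses from
#' `P(correct | theta) = c + (1 - c) F(a_i theta - tau_i)`, with
#' discrimination `a_i = lambda_i / sqrt(1 - lambda_i^2)` derived from the
#' standardized loading.
#'
#' @param config a [simulation_config()].
#' @return A list with `responses` (persons x items integer matrix),
#'   `covariates` (persons x covariates data frame, NULL when none), and
#'   `truth` (latent traits, generating loadings, difficulty targets,
#'   calibrated thresholds, guessing, covariate-trait correlations, link,
#'   seed).
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lam <- config$loadings
  a <- lam / sqrt(1 - lam^2)
  degenerate <- config$guessing >= 1
  tau <- if (degenerate) {
    rep(0, config$n_items)
  } else {
    vapply(seq_len(config$n_items), function(i) {
      calibrate_threshold(a[i], config$difficulties[i], config$guessing,
                          config$link, names(lam)[i])
    }, numeric(1))
  }
  names(tau) <- names(lam)
  out <- with_seed(config$seed, {
    q <- length(config$covariates)
    Z <- matrix(stats::rnorm(config$n_persons * (q + 1)), ncol = q + 1)
    Z <- Z %*% chol(config$joint_cor)
    theta <- Z[, 1]
    covs <- if (q) {
      d <- as.data.frame(Z[, -1, drop = FALSE])
      names(d) <- names(config$covariates)
      d
    }
    p <- if (degenerate) {
      matrix(1, config$n_persons, config$n_items)
    } else {
      vapply(seq_len(config$n_items), function(i) {
        item_response_curve(theta, a[i], tau[i], config$guessing, config$link)
      }, numeric(config$n_persons))
    }
    resp <- matrix(
      as.integer(stats::runif(length(p)) < p),
      nrow = config$n_persons, dimnames = list(NULL, names(lam))
    )
    list(responses = resp, covariates = covs, theta = theta)
  })
  truth <- list(
    latent_traits = out$theta,
    loadings = lam,
    difficulties = config$difficulties,
    thresholds = tau,
    guessing = config$guessing,
    covariate_trait_corrs = config$covariates,
    link = config$link,
    seed = config$seed
  )
  list(responses = out$responses, covariates = out$covariates, truth = truth)
}

#' A synthetic 89-item pool emulating a picture-vocabulary screening test
#'
#' Builds a [simulation_config()] whose item pool mimics a long
#' multiple-choice vocabulary instrument: 89 four-alternative items
#' (guessing floor .25), standardized loadings spanning -.03 to .81 with
#' mean near .41, difficulty targets spanning .26 to .98 with mean near .64
#' (targets below the guessing floor are excluded by construction), a
#' positive rank correlation (default .7) between loadings and easiness --
#' the confound that makes stepwise selection by loading favour easy,
#' redundant items -- and a covariate panel mixing strong convergent
#' (achievement-like), moderate, and near-zero discriminant
#' (motivation-like) trait correlations.
#'
#' @param seed integer seed; the same seed always returns the same config.
#' @param n_persons simulated sample size (default 3000).
#' @param loading_difficulty_corr rank correlation between loadings and
#'   easiness (default 0.7).
#' @return A `sim_config` with 89 items.
#' @export
make_ppvt_like_pool <- function(seed, n_persons = 3000,
                                loading_difficulty_corr = 0.7) {
  n_items <- 89L
  # deterministic Beta quantile grids mapped to the target ranges; shapes
  # chosen so the pool means sit at .41 (loadings) and .64 (difficulties)
  rescale <- function(x, lo, hi) lo + (hi - lo) * (x - min(x)) / (max(x) - min(x))
  grid <- stats::ppoints(n_items)
  loadings <- rescale(stats::qbeta(grid, 2.04, 1.8), -0.03, 0.81)
  difficulties <- rescale(stats::qbeta(grid, 2.09, 1.8), 0.26, 0.98)
  perm <- with_seed(seed, list(l = sample.int(n_items),
                               d = sample.int(n_items)))
  loadings <- loadings[perm$l]
  difficulties <- difficulties[perm$d]
  covariates <- c(
    reading_competence = 0.65, reading_speed = 0.55, math_competence = 0.45,
    reasoning = 0.40, perceptual_speed = 0.30, native_language = 0.25,
    interest_german = 0.08, motivation_german = 0.05, age = -0.05
  )
  simulation_config(
    n_persons = n_persons, loadings = loadings, difficulties = difficulties,
    guessing = 0.25, covariates = covariates,
    loading_difficulty_corr = loading_difficulty_corr,
    link = "probit", seed = seed
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d persons x %d items, guessing %.2f, %s link, seed %d\n",
    x$n_persons, x$n_items, x$guessing, x$link, x$seed))
  cat(sprintf("  loadings   mean %.3f, range [%.3f, %.3f]\n",
              mean(x$loadings), min(x$loadings), max(x$loadings)))
  cat(sprintf("  difficulty mean %.3f, range [%.3f, %.3f]\n",
              mean(x$difficulties), min(x$difficulties), max(x$difficulties)))
  if (length(x$covariates)) {
    cat(sprintf("  covariates: %s\n",
                paste(sprintf("%s (%.2f)", names(x$covariates), x$covariates),
                      collapse = ", ")))
  }
  invisible(x)
}
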