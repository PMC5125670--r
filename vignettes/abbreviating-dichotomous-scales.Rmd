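---
title: "Abbreviating dichotomous scales: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abbreviating dichotomous scales: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleshort)
```

## The problem

A long test of dichotomous (right/wrong) items is expensive to administer.
Abbreviation asks: which $k$ of the $m$ items should be kept so that the
short form still measures the same construct well? "Well" is multi-criterial:
the one-factor measurement model should fit, the composite should stay
reliable, the short form should discriminate across the ability range rather
than only at its extremes, and the short form's correlations with external
covariates should match the long form's.

The search space is enormous — `count_item_subsets(89, 25)` shows the exact
22-digit number of ways to keep 25 items out of 89 — so exhaustive search is
impossible and the package offers one greedy strategy and two metaheuristics:

* **SCOFA** (`scofa_select()`): stepwise confirmatory factor analysis;
  repeatedly drop the item with the lowest standardized loading.
* **ACO** (`aco_select()`): ant colony optimization over a four-part
  pheromone objective.
* **GA** (`ga_select()`): a genetic algorithm minimizing
  $\mathrm{cost} = I\,k + (1 - R^2)$, where $R^2$ is the variance of the
  long-form total score explained by the retained items.

## Measurement engine

### Tetrachoric correlations

Dichotomous items are modelled as thresholded bivariate normal variables.
`tetrachoric_matrix()` uses the standard two-step estimator: thresholds are
fixed at the marginal normal quantiles, and the latent correlation of each
pair maximizes the 2×2 table's likelihood (one-dimensional search). The
bivariate normal rectangle probability is computed by an angular-reduction
quadrature accurate to ~1e-10, checked in the test suite against adaptive
quadrature.

Degenerate tables get deterministic conventions: no discordant cells clamps
the estimate at +0.999, no concordant cells at −0.999, and a single empty
cell receives a 0.5 continuity correction. Because the matrix is assembled
pairwise it need not be positive semi-definite; `psd_smooth()` clips
negative eigenvalues at zero and renormalizes the diagonal. Principal
submatrices of a PSD matrix are PSD, so the smoothed full-pool matrix is
computed once and every candidate subset is fit on the corresponding
submatrix — this is what makes metaheuristic search affordable.

### One-factor fit

`fit_one_factor()` minimizes the unweighted least-squares discrepancy
$f = \sum_{i<j} (r_{ij} - \lambda_i \lambda_j)^2$ with an analytic gradient
(L-BFGS-B, loadings bounded in ±0.999 against Heywood drift). Unweighted
least squares is used deliberately instead of diagonally weighted least
squares: the asymptotic covariance matrix of 3,916 tetrachoric estimates is
neither cheap nor stable at the sample sizes involved, and ULS on the same
input preserves the ordering of candidate subsets, which is what selection
needs. Fit indices use the least-squares chi-square $T = (n-1) f_{\min}$,
the independence baseline $f_{\text{base}} = \sum_{i<j} r_{ij}^2$, and the
conventional CFI/RMSEA formulas with their degenerate cases pinned
(CFI = 1 when the baseline does not exceed the model, RMSEA = 0 when
$T \le df$).

The optimizer is started twice — once at the raw first-principal-component
loadings and once at the same direction rescaled by
$\sqrt{(e_1 - 1)\,m/(m-1)}$, which is exact for equal loadings and exactly
zero for uncorrelated items. The second start keeps the null structure at
the parsimonious all-zero solution; ties in the discrepancy are broken
toward the smaller sum of squared loadings.

Reliability is McDonald's
$\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum(1-\lambda^2))$
(`mcdonald_omega()`).

## The four-part pheromone objective

Each candidate subset is scored by `pheromone_components()`, the sum of four
logistic transforms centred exactly at conventional cutoffs:

* fit: $\varphi_{\mathrm{CFI}} = \mathrm{logit}^{-1}(100\,\mathrm{CFI} - 95)$
  and $\varphi_{\mathrm{RMSEA}} = \mathrm{logit}^{-1}(5 - 100\,\mathrm{RMSEA})$,
  averaged — 0.5 exactly at CFI = .95 and RMSEA = .05;
* reliability: $\varphi_{\omega} = \mathrm{logit}^{-1}(10\,\omega - 9)$,
  0.5 at $\omega = .90$;
* sensitivity: $\varphi_{\mathrm{sens}} = -5(M - .625)^2 + 1$, a parabola in
  the mean difficulty $M$ peaking at .625, the midpoint between a .25
  guessing floor and a perfect score. By default negative values (means
  further than ~0.45 from the peak) are clamped to 0 so that one very
  unbalanced component cannot dominate the sum; `clamp_sens = FALSE`
  retains the raw parabola;
* covariate preservation: $\varphi_{\mathrm{cor}} =
  1 - \mathrm{logit}^{-1}(100\,d - 3)$, where $d$ is the maximum absolute
  change, between short and long form, of the Pearson correlations of the
  unit-weighted sum score with each covariate — 0.5 at $d = .03$.

The total is bounded above by 4. All transforms go through `stats::plogis`,
so extreme inputs cannot overflow.

```{r}
pheromone_components(cfi = 0.97, rmsea = 0.04, omega = 0.91,
                     mean_difficulty = 0.60, max_abs_diff = 0.02)
```

## Selection strategies

### SCOFA

Fit the full pool, drop the lowest-loading item (ties broken by the lower
column index), refit on the remaining items, repeat. Because pairwise
tetrachoric estimates do not involve the other items, each refit reuses the
corresponding submatrix of the full-pool matrix. SCOFA optimizes factor
saturation only: it never looks at difficulty or covariates, which is
exactly the blind spot the metaheuristics are meant to expose. When the pool
has a positive loading–easiness confound, SCOFA systematically keeps easy
items.

### Ant colony optimization

`aco_select()` keeps a pheromone level per item, initially uniform. Each
iteration, every ant draws a $k$-item subset without replacement with
probabilities proportional to pheromone, the subsets are scored by the
four-part objective, pheromone evaporates ($\tau \leftarrow (1-\rho)\tau$),
and deposits reinforce good subsets. Non-convergent factor fits score
$-\infty$ and are logged, never fatal. The whole search is replicated
(default three times) with derived seeds and the best replication is
reported.

Two deposit rules are available. The default, `"iteration_best"`, deposits
only on the iteration's best subset, proportionally to its score. This
winner-take-all reinforcement is strongly exploitative and is the rule used
for actual abbreviation runs. Its known cost is that reinforcement feeds
back on itself: the depositing subset was itself drawn from the pheromone,
so even a completely flat objective will concentrate pheromone on whichever
items happen to get ahead early. The alternative, `"all_ants"`, has every
ant deposit its score (scaled by $1/n_{\text{ants}}$) on its items — the
classic ant-system rule. Its reinforcement is balanced across everything
sampled, so under a flat objective the pheromone stays uniform up to
sampling noise; the test suite verifies this neutrality for `"all_ants"`
specifically. The symmetric cost is weaker exploitation: at equal budgets
it reaches visibly lower objective values on large pools. The default
favours search quality; choose `"all_ants"` when diagnosing the objective
itself.

### Genetic algorithm

`ga_select()` represents candidates as inclusion masks. Parents are chosen
by rank-proportional selection, combined by uniform crossover, mutated per
position, repaired to `fixed_k` items (random add/drop) when a fixed length
is requested, and a steady-state rule replaces the worst non-elite member
when the offspring is strictly better. Fitness is $-(I\,k + 1 - R^2)$ with
$R^2$ from an ordinary least-squares regression of the full-pool total
score on the candidate's item scores. Larger item costs $I$ buy shorter
scales; `tune_item_cost()` bisects $I$ to hit a target length when, as is
typical, the cost producing a desired $k$ is not known in advance.

## Synthetic data

`simulate_responses()` draws from a guessing-affected common-factor model:
$P(X_{ij} = 1 \mid \theta_i) = c_j + (1 - c_j)\,F(a_j \theta_i - \tau_j)$
with discrimination $a_j = \lambda_j/\sqrt{1-\lambda_j^2}$. The link $F$ is
probit by default (logit with the 1.702 scaling is available); with a
probit link the marginal correct rate has a closed form, which the test
suite uses as an oracle. Thresholds are calibrated numerically
(Gauss–Hermite marginal + root finding, tolerance 1e-6) so that each item's
marginal correct rate equals its requested difficulty *including* the
guessing floor — calibration is deliberately numerical so that the probit
closed form stays an independent check rather than shared code. Covariates
are drawn jointly normal with the trait at requested correlations, and a
rank-reordering step can impose a loading–difficulty confound across items.

`make_ppvt_like_pool()` packages a fixed 89-item picture-vocabulary-like
design: right-skewed loading and difficulty distributions laid out as
deterministic Beta quantile grids (the seed only permutes item order and
drives response sampling), guessing .25 (four answer options), a +0.7
loading–easiness confound, and a nine-covariate panel with trait
correlations from .65 down to −.05.

One caveat the test suite respects: parameter-recovery checks simulate with
`guessing = 0`. A guessing floor violates the thresholded-normal model the
tetrachoric estimator assumes, biasing loadings downward; recovery is only
a clean test of the estimator when the generator and the estimator agree.
With guessing present the fitted model is an approximation — a deliberate
mirror of real multiple-choice data — and the package compares strategies
on equal footing rather than claiming unbiased parameter estimates.

## Evaluation

`evaluate_short_form()` scores any subset on the four criteria and
`compare_methods()` assembles the per-method table with the long form as
reference row, flagging good fit at CFI ≥ .95 and RMSEA ≤ .08. The
end-to-end `run_pipeline()` (and the command-line front end in
`inst/cli/scaleshort.R`) chains simulate → select → evaluate → compare and
writes all artifacts with a provenance record.

```{r, eval = FALSE}
pool <- make_ppvt_like_pool(seed = 1, n_persons = 3000)
s <- simulate_responses(pool)
corr <- tetrachoric_matrix(s$responses)

sc <- scofa_select(s$responses, k = 15, corr = corr)
ac <- aco_select(s$responses, s$covariates,
                 aco_config(k = 15, seed = 1), corr = corr)
ga <- ga_select(s$responses, ga_config(fixed_k = 15, seed = 1))

evs <- lapply(list(sc, ac, ga), function(r) {
  evaluate_short_form(s$responses, s$covariates, r$best_subset,
                      label = r$method, corr = corr)
})
compare_methods(evs, s$responses, s$covariates, corr = corr)
```

## Limitations

* The factor model is strictly unidimensional; no bifactor or
  multidimensional variants.
* ULS fit indices are comparable across subsets of the same data but are
  not the weighted-least-squares statistics a full structural equation
  package would report; absolute cutoffs should be read with that in mind.
* The tetrachoric model ignores the guessing floor; see above.
* ACO variants with pheromone bounds or rank-based deposits, and
  island-model GA parallelism, are out of scope.
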