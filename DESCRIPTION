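Package: scaleshort
Title: Item Selection Strategies for Abbreviating Dichotomous Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing short forms of long unidimensional
    dichotomous (right/wrong) scales. Implements three item-selection
    strategies: stepwise confirmatory factor analysis (SCOFA, iterative
    removal of the lowest-loading item), ant colony optimization over a
    four-part pheromone objective combining model fit (CFI, RMSEA),
    McDonald's omega reliability, mean item difficulty, and preservation
    of covariate correlations, and a genetic algorithm trading a fixed
    per-item cost against the variance of the long-form total score
    explained by the retained items. Includes the supporting categorical
    measurement machinery (tetrachoric correlations, one-factor least
    squares factor analysis on the tetrachoric matrix, fit indices,
    omega) and a seeded simulator of guessing-affected multiple-choice
    item responses with known loadings, difficulties, and trait-correlated
    covariates, so the strategies can be exercised and compared without
    access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
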