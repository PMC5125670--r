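#' Score a short form against its long form
#'
#' Evaluates a retained item subset on the four criteria used to judge
#' abbreviated scales: (a) one-factor model fit (chi-square, CFI, RMSEA),
#' (b) McDonald's omega reliability, (c) discriminatory power summarized by
#' the distribution of item difficulties (proportions correct, no guessing
#' correction), and (d) preservation of validity, the signed differences
#' between the short-form and long-form unit-weighted sum-score Pearson
#' correlations with every covariate. The pheromone breakdown of the subset
#' is attached for audit.
#'
#' @param data persons x items binary response matrix (the full pool).
#' @param covariates persons x covariates numeric table, or NULL.
#' @param subset item indices (or column names) of the short form.
#' @param label method label carried into reports.
#' @param corr optional precomputed [tetrachoric_matrix()] for `data`.
#' @param clamp_sens clamp the sensitivity pheromone below at 0.
#' @return An object of class `short_form_eval`.
#' @export
evaluate_short_form <- function(data, covariates = NULL, subset,
                                label = "short", corr = NULL,
                                clamp_sens = TRUE) {
  x <- as_response_matrix(data)
  if (is.character(subset)) {
    idx <- match(subset, colnames(x))
    if (anyNA(idx)) {
      stop(sprintf("unknown item name(s): %s",
                   paste(subset[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1 | idx > ncol(x))) {
      stop("subset indices out of range", call. = FALSE)
    }
  }
  idx <- sort(unique(idx))
  ev <- make_subset_evaluator(x, covariates, corr = corr,
                              clamp_sens = clamp_sens, cache = FALSE)
  res <- ev$evaluate(idx)
  diffs <- ev$difficulties[idx]
  lam <- res$fit$loadings
  structure(
    list(
      method = label,
      k = length(idx),
      subset = idx,
      items = colnames(x)[idx],
      cfa = res$fit,
      omega = res$fit$omega,
      mean_difficulty = mean(diffs),
      difficulty_range = range(diffs),
      loading_summary = c(min = min(lam), median = stats::median(lam),
                          mean = mean(lam), max = max(lam)),
      delta_r = res$delta_r,
      max_abs_delta_r = if (length(res$delta_r)) max(abs(res$delta_r)) else 0,
      phi = res$components,
      n_items_pool = ncol(x)
    ),
    class = "short_form_eval"
  )
}

#' @export
print.short_form_eval <- function(x, ...) {
  cat(sprintf("%s | %d items (pool %d)\n", x$method, x$k, x$n_items_pool))
  cat(sprintf(
    "  chi-square %.2f (df %d), CFI %.3f, RMSEA %.3f, omega %.3f\n",
    x$cfa$chi_square, x$cfa$df, x$cfa$cfi, x$cfa$rmsea, x$omega))
  cat(sprintf("  difficulty mean %.3f [%.3f, %.3f]; max |delta r| %.3f\n",
              x$mean_difficulty, x$difficulty_range[1], x$difficulty_range[2],
              x$max_abs_delta_r))
  invisible(x)
}

#' Side-by-side comparison of short forms and the long form
#'
#' Assembles one row per evaluated short form plus a reference row for the
#' full pool, with the model-fit, reliability, difficulty and
#' validity-preservation summaries, and flags good model fit by the
#' conventional cutoffs CFI >= .95 and RMSEA <= .08.
#'
#' @param evaluations list of [evaluate_short_form()] results, all computed
#'   on the same item pool.
#' @param data the full-pool response matrix (for the reference row).
#' @param covariates covariate table used in the evaluations, or NULL.
#' @param corr optional precomputed [tetrachoric_matrix()] for `data`.
#' @return A data frame of class `short_form_comparison` with columns
#'   method, k, chi_square, df, cfi, rmsea, omega, mean_difficulty,
#'   max_abs_delta_r, good_fit; the reference row is last.
#' @export
compare_methods <- function(evaluations, data, covariates = NULL,
                            corr = NULL) {
  if (inherits(evaluations, "short_form_eval")) {
    evaluations <- list(evaluations)
  }
  if (!length(evaluations)) stop("need at least one evaluation", call. = FALSE)
  pool_sizes <- vapply(evaluations, `[[`, numeric(1), "n_items_pool")
  x <- as_response_matrix(data)
  if (any(pool_sizes != ncol(x))) {
    stop("evaluations were computed on a different item pool", call. = FALSE)
  }
  ref <- evaluate_short_form(x, covariates, subset = seq_len(ncol(x)),
                             label = "long form", corr = corr)
  rows <- lapply(c(evaluations, list(ref)), function(e) {
    data.frame(
      method = e$method, k = e$k,
      chi_square = e$cfa$chi_square, df = e$cfa$df,
      cfi = e$cfa$cfi, rmsea = e$cfa$rmsea, omega = e$omega,
      mean_difficulty = e$mean_difficulty,
      max_abs_delta_r = e$max_abs_delta_r,
      good_fit = e$cfa$cfi >= 0.95 & e$cfa$rmsea <= 0.08,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("short_form_comparison", "data.frame")
  out
}

#' @export
print.short_form_comparison <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
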