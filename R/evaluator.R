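# Shared machinery for scoring candidate item subsets.
#
# The expensive ingredients -- the full-pool tetrachoric matrix, item
# difficulties, the long-form sum score and its covariate correlations --
# depend only on the data, so they are computed once; any principal
# submatrix of the smoothed (PSD) tetrachoric matrix is itself PSD and can
# be fitted directly. Subset scores are memoized under the canonical sorted
# key, which bounds the number of factor-model fits by the number of
# distinct subsets visited.

make_subset_evaluator <- function(data, covariates = NULL, corr = NULL,
                                  clamp_sens = TRUE, cache = TRUE) {
  x <- as_response_matrix(data)
  if (is.null(corr)) corr <- tetrachoric_matrix(x)
  stopifnot(inherits(corr, "corr_matrix"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(x)) {
      stop("covariate rows must align with response rows", call. = FALSE)
    }
  }
  difficulties <- colMeans(x)
  long_sum <- rowSums(x)
  r_long <- if (!is.null(covariates) && ncol(covariates)) {
    vapply(covariates, function(v) stats::cor(long_sum, as.numeric(v),
                                              use = "complete.obs"),
           numeric(1))
  } else {
    numeric()
  }
  store <- if (cache) new.env(parent = emptyenv())

  evaluate <- function(idx) {
    idx <- sort(as.integer(idx))
    key <- paste(idx, collapse = ",")
    if (cache && !is.null(store[[key]])) return(store[[key]])
    fit <- fit_one_factor(corr$values[idx, idx, drop = FALSE],
                          n_persons = corr$n_persons)
    delta_r <- if (length(r_long)) {
      short_sum <- rowSums(x[, idx, drop = FALSE])
      r_short <- vapply(covariates, function(v) {
        stats::cor(short_sum, as.numeric(v), use = "complete.obs")
      }, numeric(1))
      r_short - r_long
    } else {
      numeric()
    }
    max_dr <- if (length(delta_r)) max(abs(delta_r)) else 0
    comp <- pheromone_components(
      cfi = fit$cfi, rmsea = fit$rmsea, omega = fit$omega,
      mean_difficulty = mean(difficulties[idx]),
      max_abs_diff = min(max_dr, 2), clamp = clamp_sens
    )
    out <- list(
      fit = fit,
      components = comp,
      delta_r = delta_r,
      total = if (fit$converged) comp$total else -Inf
    )
    if (cache) store[[key]] <- out
    out
  }

  list(
    evaluate = evaluate,
    n_items = ncol(x),
    item_ids = colnames(x),
    difficulties = difficulties,
    long_sum = long_sum,
    r_long = r_long,
    corr = corr
  )
}

new_selection_result <- function(method, best_subset, item_ids, best_score,
                                 trajectory, seeds, evaluations, config,
                                 ...) {
  best_subset <- sort(as.integer(best_subset))
  structure(
    list(
      method = method,
      best_subset = best_subset,
      best_items = item_ids[best_subset],
      k = length(best_subset),
      n_items = length(item_ids),
      best_score = best_score,
      trajectory = trajectory,
      seeds = seeds,
      evaluations = evaluations,
      config = config,
      ...
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection: %d of %d items, score %.4f (%d evaluations)\n",
              x$method, x$k, x$n_items %||% length(x$best_items),
              x$best_score, x$evaluations))
  cat("  items:", paste(x$best_items, collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.selection_result <- function(object, ...) {
  print(object)
  if (length(object$trajectory)) {
    cat(sprintf("  trajectory: %d steps, from %.4f to %.4f\n",
                length(object$trajectory), object$trajectory[1],
                object$trajectory[length(object$trajectory)]))
  }
  if (!is.null(object$seeds)) {
    cat("  seeds:", paste(object$seeds, collapse = ", "), "\n")
  }
  invisible(object)
}
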