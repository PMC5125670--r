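#' Stepwise confirmatory factor analysis (SCOFA) item selection
#'
#' The classical stepwise abbreviation heuristic: fit the one-factor model
#' to the full pool, remove the single item with the lowest standardized
#' loading, refit on the reduced set, and repeat until `k` items remain.
#' Ties in the lowest loading are broken by the lower item index. Because
#' pairwise tetrachoric estimates do not change when other items are
#' dropped, the tetrachoric matrix is computed once and each refit uses the
#' corresponding principal submatrix.
#'
#' @param data persons x items binary response matrix.
#' @param k target short-form length (`2 <= k < ncol(data)`; the final
#'   refit is reported only when `k >= 3`, the minimum for a one-factor
#'   model).
#' @param corr optional precomputed [tetrachoric_matrix()] for `data`.
#' @return A `selection_result` with the retained subset, the final minimum
#'   loading as `best_score`, the per-step minimum loadings as `trajectory`,
#'   and the `removal_order` (item indices, first removed first).
#' @export
scofa_select <- function(data, k, corr = NULL) {
  x <- as_response_matrix(data)
  m <- ncol(x)
  if (k < 2 || k >= m) stop("need 2 <= k < number of items", call. = FALSE)
  if (is.null(corr)) corr <- tetrachoric_matrix(x)
  V <- corr$values
  dimnames(V) <- list(colnames(x), colnames(x))
  keep <- seq_len(m)
  removal_order <- integer()
  trajectory <- numeric()
  evaluations <- 0L
  fit <- NULL
  while (length(keep) > k) {
    fit <- fit_one_factor(V[keep, keep, drop = FALSE],
                          n_persons = corr$n_persons)
    evaluations <- evaluations + 1L
    if (!fit$converged) {
      cond <- structure(
        class = c("scofa_nonconvergence", "error", "condition"),
        list(
          message = sprintf(
            "one-factor fit failed to converge with %d items; partial removal order attached",
            length(keep)),
          call = NULL,
          removal_order = removal_order,
          remaining = keep
        )
      )
      stop(cond)
    }
    # lowest loading; ties broken by lower item index
    drop_pos <- which.min(fit$loadings)
    trajectory <- c(trajectory, fit$loadings[drop_pos])
    removal_order <- c(removal_order, keep[drop_pos])
    keep <- keep[-drop_pos]
  }
  final <- if (k >= 3L) {
    f <- fit_one_factor(V[keep, keep, drop = FALSE],
                        n_persons = corr$n_persons)
    evaluations <- evaluations + 1L
    f
  } else {
    fit # k = 2: loadings of the retained pair from the last 3-item fit
  }
  final_min <- min(final$loadings[names(final$loadings) %in% colnames(x)[keep]])
  new_selection_result(
    method = "SCOFA",
    best_subset = keep,
    item_ids = colnames(x),
    best_score = final_min,
    trajectory = trajectory,
    seeds = integer(),
    evaluations = evaluations,
    config = list(k = k),
    removal_order = removal_order,
    final_fit = final
  )
}
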