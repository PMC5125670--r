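# Delimited-text readers/writers and JSON serialization for audit trails.

#' Read and write binary response matrices
#'
#' Responses travel as comma-delimited text with a header row of item names
#' and one row per person; every cell must be 0 or 1.
#'
#' @param path file path.
#' @param data persons x items binary matrix.
#' @return `read_response_matrix()` returns an integer matrix with item
#'   names; `write_response_matrix()` returns `path` invisibly.
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate item names in header", call. = FALSE)
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    ok <- !is.na(v) & (v == 0 | v == 1)
    if (!all(ok)) {
      stop(sprintf("non-binary value at row %d, column '%s'",
                   which(!ok)[1L], names(df)[j]), call. = FALSE)
    }
  }
  as_response_matrix(df)
}

#' @rdname read_response_matrix
#' @export
write_response_matrix <- function(data, path) {
  x <- as_response_matrix(data)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read and write covariate tables
#'
#' Numeric persons x covariates tables as comma-delimited text with a
#' header row.
#'
#' @param path file path.
#' @param covariates data frame of numeric covariates.
#' @return `read_covariates()` returns a data frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  not_num <- !vapply(df, is.numeric, logical(1))
  if (any(not_num)) {
    stop(sprintf("non-numeric covariate column '%s'",
                 names(df)[not_num][1L]), call. = FALSE)
  }
  df
}

#' @rdname read_covariates
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(as.data.frame(covariates), path, row.names = FALSE)
  invisible(path)
}

#' Serialize simulation ground truth as JSON
#'
#' Stores the generating parameters exactly as used, so a simulated data
#' set can be audited and regenerated.
#'
#' @param truth the `truth` element of a [simulate_responses()] result.
#' @param path file path.
#' @return `read_truth_record()` returns the truth list.
#' @export
write_truth_record <- function(truth, path) {
  payload <- truth
  # named per-item/per-covariate vectors become JSON objects, keeping names
  for (f in c("loadings", "difficulties", "thresholds",
              "covariate_trait_corrs")) {
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loadings", "difficulties", "thresholds",
              "covariate_trait_corrs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  raw
}

#' Serialize a selection result as JSON
#'
#' Writes the method, retained item names (1-based column identifiers), the
#' best score, score trajectory, seeds, evaluation count, and a config echo.
#'
#' @param result a `selection_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  payload <- list(
    method = result$method,
    k = result$k,
    items = result$best_items,
    item_indices = result$best_subset,
    best_score = result$best_score,
    trajectory = result$trajectory,
    seeds = result$seeds,
    evaluations = result$evaluations,
    config = unclass(result$config)
  )
  for (f in c("replication_scores", "removal_order", "r_squared", "cost")) {
    if (!is.null(result[[f]])) payload[[f]] <- result[[f]]
  }
  if (!is.null(result$components)) {
    payload$components <- unclass(result$components)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a one-factor fit as JSON
#'
#' @param fit a `onefactor_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cfa_fit <- function(fit, path) {
  stopifnot(inherits(fit, "onefactor_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
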