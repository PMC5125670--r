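# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never clobber the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Canonical string key for a set of item indices (sorted, so equality is
# set equality).
subset_key <- function(idx) paste(sort(as.integer(idx)), collapse = ",")

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                  open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  bad_lo <- if (open_lo) x <= lo else x < lo
  bad_hi <- if (open_hi) x >= hi else x > hi
  if (bad_lo || bad_hi) {
    stop(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

# Validate a persons x items binary matrix and return it as an integer
# matrix with item names.
as_response_matrix <- function(data) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("item", seq_len(ncol(x)))
  }
  storage.mode(x) <- "integer"
  bad <- which(!(x %in% c(0L, 1L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    stop(sprintf(
      "response matrix must be binary; found non-{0,1} value at row %d, column '%s'",
      rc[1L], colnames(x)[rc[2L]]
    ), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate item names in response matrix", call. = FALSE)
  }
  x
}
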