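# Tetrachoric correlations under the bivariate-normal liability model.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; computed once.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      i <- seq_len(n - 1)
      b <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- b
      J[cbind(i + 1, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      cache[[key]] <<- list(nodes = e$values,
                            weights = 2 * e$vectors[1, ]^2)
    }
    cache[[key]]
  }
})

# Standard bivariate normal CDF P(X <= h, Y <= k), correlation rho, via the
# single-integral angular reduction
#   Phi2 = Phi(h) Phi(k) + (1/2pi) Int_0^{asin rho}
#            exp(-(h^2 + k^2 - 2 h k sin u) / (2 cos^2 u)) du,
# whose integrand is smooth on [0, asin rho] even for |rho| near 1.
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-12)
  gl <- gauss_legendre(24L)
  a <- asin(rho)
  u <- a / 2 * (gl$nodes + 1)
  s <- sin(u)
  c2 <- cos(u)^2
  integrand <- exp(-(h^2 + k^2 - 2 * h * k * s) / (2 * c2))
  stats::pnorm(h) * stats::pnorm(k) +
    a / 2 * sum(gl$weights * integrand) / (2 * pi)
}

# Two-step ML tetrachoric for one 2x2 table of counts
# (n11, n10, n01, n00; first index = item 1 correct). Thresholds are fixed
# at the normal quantiles of the margins; rho maximizes the multinomial
# likelihood by Brent search.
tetrachoric_pair <- function(n11, n10, n01, n00, r_max = 0.999) {
  # boundary tables: no discordant (or no concordant) pairs at all
  if (n10 == 0 && n01 == 0) return(r_max)
  if (n11 == 0 && n00 == 0) return(-r_max)
  counts <- c(n11, n10, n01, n00)
  counts[counts == 0] <- 0.5 # continuity correction for single empty cells
  n <- sum(counts)
  p1 <- (counts[1] + counts[2]) / n
  p2 <- (counts[1] + counts[3]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  s1 <- 1 - stats::pnorm(t1)
  s2 <- 1 - stats::pnorm(t2)
  negll <- function(r) {
    p11 <- 1 - stats::pnorm(t1) - stats::pnorm(t2) + pbvnorm(t1, t2, r)
    p10 <- s1 - p11
    p01 <- s2 - p11
    p00 <- 1 - p11 - p10 - p01
    p <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(counts * log(p))
  }
  opt <- stats::optimize(negll, interval = c(-r_max, r_max), tol = 1e-7)
  max(min(opt$minimum, r_max), -r_max)
}

#' Tetrachoric correlation matrix of a binary response matrix
#'
#' Estimates, for every item pair, the correlation of the latent
#' bivariate-normal liabilities implied by the 2x2 cross-classification of
#' responses (maximum likelihood with thresholds fixed at the normal
#' quantiles of the item margins). Tables with no discordant (or no
#' concordant) responses are mapped to +/- `r_max`; single empty cells
#' receive a 0.5 continuity correction before estimation. The assembled
#' matrix is smoothed to positive semidefiniteness by clipping negative
#' eigenvalues at zero and rescaling the diagonal back to 1, since pairwise
#' estimates need not be jointly consistent.
#'
#' @param data persons x items binary (0/1) matrix or data frame with item
#'   names as column names.
#' @param r_max clamp applied at the correlation boundary (default 0.999).
#' @return An object of class `corr_matrix`: list with `values` (the smoothed
#'   symmetric matrix), `item_ids`, and `n_persons`.
#' @export
tetrachoric_matrix <- function(data, r_max = 0.999) {
  x <- as_response_matrix(data)
  m <- ncol(x)
  if (m < 2L) stop("need at least 2 items", call. = FALSE)
  csum <- colSums(x)
  const <- which(csum == 0L | csum == nrow(x))
  if (length(const)) {
    stop(sprintf(
      "item '%s' is constant; its liability threshold is undefined",
      colnames(x)[const[1L]]
    ), call. = FALSE)
  }
  R <- diag(m)
  for (i in seq_len(m - 1L)) {
    xi <- x[, i]
    for (j in (i + 1L):m) {
      xj <- x[, j]
      n11 <- sum(xi & xj)
      n10 <- sum(xi) - n11
      n01 <- sum(xj) - n11
      n00 <- nrow(x) - n11 - n10 - n01
      R[i, j] <- R[j, i] <- tetrachoric_pair(n11, n10, n01, n00, r_max)
    }
  }
  R <- psd_smooth(R)
  dimnames(R) <- list(colnames(x), colnames(x))
  structure(
    list(values = R, item_ids = colnames(x), n_persons = nrow(x)),
    class = "corr_matrix"
  )
}

# Clip negative eigenvalues at 0 and renormalize to unit diagonal.
psd_smooth <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) {
    return((R + t(R)) / 2)
  }
  v <- pmax(e$values, 0)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(M), .Machine$double.eps))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  (M + t(M)) / 2
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("Tetrachoric correlation matrix: %d items, n = %d persons\n",
              length(x$item_ids), x$n_persons))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  mean r = %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  invisible(x)
}
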