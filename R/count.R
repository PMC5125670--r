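#' Exact size of the item-subset search space
#'
#' Number of distinct ways to retain `k` of `n` items, i.e. the binomial
#' coefficient C(n, k), computed in exact integer arithmetic. For realistic
#' scale-abbreviation problems (e.g. 25 out of 89 items) the count has more
#' than 20 decimal digits and overflows double precision, so the exact value
#' is returned as a decimal string alongside a (possibly rounded) numeric.
#'
#' @param n pool size (number of items in the long form).
#' @param k short-form length.
#' @return A list with elements `digits` (exact decimal string), `value`
#'   (numeric, rounded when the count exceeds 2^53), and `exact_numeric`
#'   (TRUE when `value` represents the count exactly).
#' @examples
#' count_item_subsets(10, 4)$value   # 210
#' count_item_subsets(89, 25)$digits # a 22-digit number
#' @export
count_item_subsets <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || is.na(k) || n < 0L || k < 0L || k > n) {
    stop("need 0 <= k <= n", call. = FALSE)
  }
  k <- min(k, n - k)
  # big integer as little-endian vector of base-1e4 limbs
  x <- 1
  for (i in seq_len(k)) {
    x <- bigint_mul_small(x, n - k + i)
    x <- bigint_div_small(x, i) # exact: running value is C(n-k+i, i)
  }
  digits <- bigint_format(x)
  value <- as.numeric(digits)
  list(digits = digits, value = value,
       exact_numeric = value <= 2^53 && value == sum(x * 1e4^(seq_along(x) - 1)))
}

bigint_mul_small <- function(x, m) {
  carry <- 0
  for (i in seq_along(x)) {
    v <- x[i] * m + carry
    x[i] <- v %% 1e4
    carry <- v %/% 1e4
  }
  while (carry > 0) {
    x <- c(x, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  x
}

bigint_div_small <- function(x, d) {
  rem <- 0
  for (i in rev(seq_along(x))) {
    v <- rem * 1e4 + x[i]
    x[i] <- v %/% d
    rem <- v %% d
  }
  if (rem != 0) stop("non-exact big-integer division") # internal invariant
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

bigint_format <- function(x) {
  limbs <- rev(x)
  out <- c(format(limbs[1L], scientific = FALSE),
           sprintf("%04d", limbs[-1L]))
  paste(out, collapse = "")
}
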