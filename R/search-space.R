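# Exact size of the module search space. With thousands of orthogroups the
# number of candidate modules of size 3-10 runs to ~10^34 — far beyond
# 64-bit integers and beyond exact double arithmetic — which is why the
# method tests pairwise interactions instead of scoring modules directly.
# A tiny exact big-integer arithmetic layer (base-1e7 digit vectors) keeps
# the count exact; no installed R package provides arbitrary-precision
# integers.

BIG_BASE <- 1e7

big_from <- function(n) {
  stopifnot(n >= 0, n < 2^53)
  digits <- numeric(0)
  repeat {
    digits <- c(digits, n %% BIG_BASE)
    n <- n %/% BIG_BASE
    if (n == 0) break
  }
  digits
}

big_norm <- function(x) {
  carry <- 0
  for (i in seq_along(x)) {
    v <- x[i] + carry
    x[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    x <- c(x, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiplier must stay below BIG_BASE so digit products fit exactly
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < BIG_BASE)
  big_norm(a * s)
}

# exact division by a small integer (remainder must be zero)
big_div_small <- function(a, s) {
  stopifnot(s >= 1, s < BIG_BASE)
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * BIG_BASE + a[i]
    out[i] <- v %/% s
    rem <- v %% s
  }
  stopifnot(rem == 0)
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_choose <- function(n, k) {
  if (k < 0 || k > n) return(big_from(0))
  k <- min(k, n - k)
  r <- big_from(1)
  for (i in seq_len(k)) {
    r <- big_div_small(big_mul_small(r, n - k + i), i)
  }
  r
}

big_to_string <- function(x) {
  parts <- sprintf("%07.0f", rev(x))
  parts[1] <- sub("^0+(?=\\d)", "", parts[1], perl = TRUE)
  paste(parts, collapse = "")
}

#' Exact count of candidate modules
#'
#' Number of distinct smCOG sets of size `min_size` to `max_size` that can
#' be formed from `n_smcogs` orthogroups: the sum of binomial coefficients
#' `C(n_smcogs, k)` over the size range, computed with exact integer
#' arithmetic. For realistic collections this is astronomically large,
#' which motivates the pairwise-interaction approach.
#'
#' @param n_smcogs Number of orthogroups available.
#' @param min_size,max_size Module size range (defaults 3 and 10).
#' @return A list with `value` (the count as a double, possibly losing
#'   precision beyond ~15 significant digits), `exact` (the full count as
#'   a decimal string), and `n_digits`.
#' @examples
#' module_search_space(100)$exact
#' @export
module_search_space <- function(n_smcogs, min_size = 3, max_size = 10) {
  stopifnot(n_smcogs >= 1, min_size >= 1, max_size >= min_size)
  total <- big_from(0)
  for (k in min_size:max_size) {
    total <- big_add(total, big_choose(n_smcogs, k))
  }
  s <- big_to_string(total)
  list(
    value = as.numeric(s),
    exact = s,
    n_digits = nchar(s)
  )
}
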