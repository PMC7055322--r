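# Minimal exact non-negative integer arithmetic (base 1e7 digit vectors,
# least-significant first) sufficient for exact binomial coefficients far
# beyond 2^53. Only multiply-by-small and exact divide-by-small are needed.

BIG_BASE <- 1e7

big_from_int <- function(n) {
  if (n == 0) return(0)
  digits <- numeric(0)
  while (n > 0) {
    digits <- c(digits, n %% BIG_BASE)
    n <- n %/% BIG_BASE
  }
  digits
}

big_mul_small <- function(a, m) {
  carry <- 0
  for (i in seq_along(a)) {
    v <- a[i] * m + carry
    a[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  while (carry > 0) {
    a <- c(a, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  a
}

big_div_small <- function(a, d) { # exact division assumed
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * BIG_BASE + a[i]
    a[i] <- v %/% d
    rem <- v %% d
  }
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_to_string <- function(a) {
  paste0(a[length(a)],
         paste(sprintf("%07d", rev(a[-length(a)])), collapse = ""))
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

# Exact binomial coefficient choose(n, k) as a digit vector; the running
# product r * (n - k + i) / i is integral at every step i.
big_choose <- function(n, k) {
  k <- min(k, n - k)
  if (k < 0) return(big_from_int(0))
  r <- big_from_int(1)
  for (i in seq_len(k)) {
    r <- big_mul_small(r, n - k + i)
    r <- big_div_small(r, i)
  }
  r
}

#' Size of the landscape search space
#'
#' Exact number of multisets of `L` slots filled with replacement from
#' `n_plots` plots: \eqn{\binom{n_plots + L - 1}{L}}, computed in exact
#' integer arithmetic (the 32-over-32 case, 916312070471295267, exceeds
#' what doubles represent exactly).
#'
#' @param L Landscape size (number of slots).
#' @param n_plots Number of distinct plots available.
#' @return A double approximation of the count, with the exact decimal
#'   representation in attribute `"exact"`.
#' @export
#' @examples
#' search_space_size(2, 2)                  # 3
#' attr(search_space_size(32, 32), "exact") # "916312070471295267"
search_space_size <- function(L, n_plots) {
  stopifnot(L >= 1, n_plots >= 1)
  b <- big_choose(n_plots + L - 1, L)
  structure(big_to_double(b), exact = big_to_string(b))
}
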