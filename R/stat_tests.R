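#' Upper-tail hypergeometric probability for shared miRNA counts
#'
#' The significance of two mRNAs sharing `k` targeting miRNAs when one is
#' targeted by `K` miRNAs, the other by `n`, out of a universe of `N`
#' miRNAs: `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, i.e.
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`. With `k = 0` the whole
#' support is covered and the value is exactly 1. The same kernel is the
#' over-representation test of [ora_enrich()].
#'
#' All arguments are vectorized and recycled.
#'
#' @param k Observed shared count(s), `0 <= k <= min(K, n)`.
#' @param K Number of miRNAs targeting the first mRNA (successes in the
#'   population).
#' @param n Number of miRNAs targeting the second mRNA (draws).
#' @param N miRNA universe size.
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @export
#' @examples
#' hypergeom_shared_pvalue(3, 4, 3, 10)  # 4/120
hypergeom_shared_pvalue <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  bad <- !is.finite(k) | !is.finite(K) | !is.finite(n) | !is.finite(N) |
    k < 0 | K < 0 | n < 0 | K > N | n > N | k > K | k > n
  if (any(bad)) {
    ct_stop("hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N",
            class = "cerna_bad_input")
  }
  # upper tail P(X >= k); phyper's lower.tail=FALSE gives P(X > q)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation of two vectors with the classical t-based
#' two-sided p-value: `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom; `|r| = 1` returns `p = 0`. This is the co-expression test of
#' the ceRNA screen.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each non-constant.
#' @return List with elements `r` and `p`.
#' @export
#' @examples
#' pearson_test(1:5, c(2, 1, 4, 3, 6))
pearson_test <- function(x, y) {
  if (length(x) != length(y)) {
    ct_stop("'x' and 'y' must have equal length", class = "cerna_bad_input")
  }
  n <- length(x)
  if (n < 3L) ct_stop("need n >= 3 observations", class = "cerna_bad_input")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    ct_stop("non-finite values in correlation input", class = "cerna_bad_input")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  sy <- sum(yc^2)
  if (sx == 0 || sy == 0) {
    ct_stop("constant vector: correlation undefined",
            class = "cerna_constant_input")
  }
  r <- sum(xc * yc) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  list(r = r, p = cor_pvalue(r, n))
}

# two-sided p for a vector/matrix of Pearson r at sample size n
cor_pvalue <- function(r, n) {
  p <- r
  one <- abs(r) >= 1
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[one] <- 0
  p
}
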