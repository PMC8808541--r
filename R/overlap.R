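.checkOverlapCounts <- function(x, n, D, N) {
  if (any(c(x, n, D, N) < 0) || n > N || D > N || x > min(n, D))
    stop("inconsistent counts: need 0 <= x <= min(n, D) and n, D <= N")
}

#' Exact hypergeometric upper tail in log-space
#'
#' P(X >= x) for X ~ Hypergeometric(N, D, n): the probability that two
#' sets of sizes n and D drawn at random from a universe of N markers
#' share at least x members. Computed term-wise with log binomial
#' coefficients combined by log-sum-exp, so universes of several hundred
#' thousand markers are handled without overflowing the factorials that
#' make the naive form uncomputable.
#'
#' @param x overlap count.
#' @param n,D the two set sizes.
#' @param N universe size.
#' @return upper-tail probability.
#' @examples
#' hypergeomUpperTail(4, 4, 5, 10)   # 5/210
#' @export
hypergeomUpperTail <- function(x, n, D, N) {
  .checkOverlapCounts(x, n, D, N)
  if (x == 0) return(1)
  ks <- x:min(n, D)
  lt <- lchoose(D, ks) + lchoose(N - D, n - ks) - lchoose(N, n)
  m <- max(lt)
  min(exp(m + log(sum(exp(lt - m)))), 1)  # guard rounding at x near 0
}

#' Normal approximation to the overlap tail
#'
#' With p = D/N and q = 1 - p, the continuity-corrected deviate is
#' Z = |x - 0.5 - n p| / sqrt(n p q) and the upper-tail probability is
#' the standard-normal survival function, expressed through the error
#' function as (1 - erf(Z / sqrt(2))) / 2.
#'
#' @inheritParams hypergeomUpperTail
#' @return list with \code{Z} and \code{p}.
#' @export
normalApproxTail <- function(x, n, D, N) {
  .checkOverlapCounts(x, n, D, N)
  p <- D / N; q <- 1 - p
  if (n * p * q == 0) stop("degenerate parameters: n*p*q = 0")
  Z <- abs((x - 0.5 - n * p) / sqrt(n * p * q))
  # survival via erfc: (1 - erf(z/sqrt(2)))/2 == pnorm(z, lower.tail = FALSE)
  list(Z = Z, p = (1 - .erf(Z / sqrt(2))) / 2)
}

.erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1

#' Overlap significance with automatic method selection
#'
#' Uses the normal approximation when its validity condition holds —
#' p - 2 sqrt(p q / n) > 0 (the +/- band stays positive) and 10 n < N —
#' and the exact log-space hypergeometric tail otherwise. Sparse overlaps
#' such as a hundred selected markers against a clock set in a 4e5-probe
#' universe fail the condition and take the exact branch.
#'
#' @inheritParams hypergeomUpperTail
#' @param method "auto" (the switching rule), "exact" or "normal".
#' @return an \linkS4class{OverlapTest}.
#' @examples
#' overlapProbability(8, 103, 71, 432924)
#' @export
overlapProbability <- function(x, n, D, N, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  .checkOverlapCounts(x, n, D, N)
  p <- D / N; q <- 1 - p
  useNormal <- switch(method,
    auto = (p - 2 * sqrt(p * q / n) > 0) && (n * 10 < N),
    exact = FALSE,
    normal = TRUE)
  if (useNormal) {
    na <- normalApproxTail(x, n, D, N)
    new("OverlapTest", x = x, n = n, D = D, N = N, p = na$p,
        method = "normal_approx", Z = na$Z)
  } else {
    new("OverlapTest", x = x, n = n, D = D, N = N,
        p = hypergeomUpperTail(x, n, D, N), method = "exact", Z = NA_real_)
  }
}
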