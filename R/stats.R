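#' Exact McNemar test on discordant counts
#'
#' Exact two-sided binomial test of the two discordant counts against a fair
#' coin, the appropriate form when discordant pairs are few. The degenerate
#' case b = c = 0 returns p = 1 by convention.
#'
#' @param b,c discordant counts (method-1-only and method-2-only
#'   detections).
#' @return two-sided p-value.
#' @export
#' @examples
#' mcnemar_exact(20, 0)   # ~1.9e-6
#' mcnemar_exact(0, 0)    # 1
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative", call. = FALSE)
  n <- b + c
  if (n == 0) return(1)
  stats::binom.test(b, n, p = 0.5, alternative = "two.sided")$p.value
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard convention); an all-zero
#' difference vector returns p = 1. The exact signed-rank distribution is
#' used for n <= 25 untied differences, the continuity-corrected normal
#' approximation otherwise.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !tied) {
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
  } else {
    mu <- n * (n + 1) / 4
    ties_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties_tab^3 - ties_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(p, 1)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant vector has no
#' rank ordering; the coefficient is undefined and returned as `NA` with a
#' warning.
#'
#' @param x,y paired numeric vectors, at least 3 complete pairs.
#' @return the correlation coefficient rs.
#' @export
spearman_rs <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
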