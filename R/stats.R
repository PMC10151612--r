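#' Wilcoxon signed-rank test from its definition
#'
#' Two-sided paired test on `x - y`. Zero differences are dropped, absolute
#' differences are ranked (midranks for ties), and the statistic is the sum
#' of ranks of positive differences. The null distribution is exact (via the
#' signed-rank distribution) for n <= 25 without ties, and a normal
#' approximation with tie correction and continuity correction otherwise.
#' Implemented from the definition so the package's statistical surface is
#' itself testable; agreement with [stats::wilcox.test()] is checked in the
#' test suite.
#'
#' @param x,y paired numeric vectors.
#' @return List: `statistic` (V, rank sum of positive differences), `n`
#'   (nonzero pairs), `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
signrank_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, n = 0L, p_value = 1,
                method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    # P(W >= V) and P(W <= V) under the exact signed-rank null
    p <- 2 * min(stats::psignrank(V - 1, n, lower.tail = FALSE),
                 stats::psignrank(V, n))
    list(statistic = V, n = n, p_value = min(1, p), method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    list(statistic = V, n = n,
         p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' One-way ANOVA from the sum-of-squares definitions
#'
#' Classical between/within decomposition over `k` groups. With zero
#' within-group variance and nonzero between-group variance the F statistic
#' is infinite; the p-value is then reported as 0 with `degenerate = TRUE`.
#'
#' @param groups list of numeric vectors (one per group).
#' @return List: `F`, `df_between`, `df_within`, `p_value`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  k <- length(groups)
  if (k < 2) stop("ANOVA needs at least two groups with >= 2 observations")
  ns <- vapply(groups, length, numeric(1))
  ms <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * ms) / sum(ns)
  ssb <- sum(ns * (ms - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1; dfw <- sum(ns) - k
  if (ssw <= 0) {
    if (ssb <= 0)
      return(list(F = 0, df_between = dfb, df_within = dfw, p_value = 1,
                  degenerate = TRUE))
    return(list(F = Inf, df_between = dfb, df_within = dfw, p_value = 0,
                degenerate = TRUE))
  }
  Fstat <- (ssb / dfb) / (ssw / dfw)
  list(F = Fstat, df_between = dfb, df_within = dfw,
       p_value = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
       degenerate = FALSE)
}
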