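#' @title Shared statistical primitives
#' @description Every stage funnels its hypothesis testing through the
#'   four primitives here, so sidedness, tie handling and FDR conventions
#'   are defined once: two-sided Mann-Whitney U, Benjamini-Hochberg
#'   step-up FDR, Spearman rank correlation on midranks, and the
#'   hypergeometric upper tail used by over-representation analysis.
#' @name stats_core
NULL

#' Two-sided Mann-Whitney U test
#'
#' U is reported for the first group (x).  The p-value is exact by
#' enumeration when the combined sample size is at most 12 and the data
#' carry no ties; otherwise the normal approximation with tie and
#' continuity correction is used (the branch [stats::wilcox.test()] takes
#' in that regime).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with elements `U`, `p`, `exact` (logical).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (n1 + n2) <= 12 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  # degenerate pooled sample (every value tied): no evidence either way
  if (is.nan(p)) p <- 1
  list(U = U, p = min(p, 1), exact = use_exact)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA`/`NaN` p-values propagate as `NA`, q is
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of midranks; the p-value uses the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom (the asymptotic branch of [stats::cor.test()]), which keeps
#' ties well-defined.  Zero rank variance in either argument leaves rho
#' undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `undefined` (TRUE when a rank variance
#'   is zero, in which case `rho` and `p` are `NA`).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    return(list(rho = NA_real_, p = NA_real_, undefined = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability of observing at least `k` pathway members in a random
#' draw of `n` metabolites from a universe of `N` containing `K`
#' members: the ORA enrichment p-value.
#'
#' @param N universe size.
#' @param K pathway size (successes in the universe).
#' @param n query size (number drawn).
#' @param k observed hits.
#' @return upper-tail probability.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts (need k <= min(K, n) <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
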