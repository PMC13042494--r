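#' One-sided hypergeometric overlap test
#'
#' Tests whether the overlap of two gene sets drawn from a common universe is
#' larger than chance ("greater" alternative): p = P(X >= k) with
#' X ~ Hypergeometric(universe, n1, n2).
#'
#' @param k Observed overlap size.
#' @param n1,n2 Sizes of the two sets.
#' @param universe Background universe size (e.g. all expressed genes).
#' @return The one-sided enrichment p-value.
#' @export
#' @examples
#' hypergeom_overlap(k = 5, n1 = 5, n2 = 5, universe = 20)  # 1 / choose(20, 5)
hypergeom_overlap <- function(k, n1, n2, universe) {
  vals <- c(k, n1, n2, universe)
  if (any(!is.finite(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
    abort("k, n1, n2 and universe must be non-negative integers",
          class = "cscore_domain_error")
  }
  if (n1 > universe || n2 > universe) {
    abort("set sizes cannot exceed the universe", class = "cscore_domain_error")
  }
  if (k > min(n1, n2)) {
    abort("overlap cannot exceed the smaller set", class = "cscore_domain_error")
  }
  phyper(k - 1, n1, universe - n1, n2, lower.tail = FALSE)
}

#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes the exact two-sided p-value of the Mann-Whitney U statistic by
#' enumerating all `choose(n1 + n2, n1)` assignments of the pooled ranks to
#' the first group. Suitable for small samples with no ties across groups
#' (exact enumeration assumes distinct values; ties raise an error).
#'
#' The default two-sided p is twice the smaller tail probability, capped at
#' 1 (`tail_method = "doubled"`); `"symmetric"` instead sums the probability
#' of all U at least as far from the null mean n1*n2/2 as the observed U.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param tail_method `"doubled"` (default) or `"symmetric"`.
#' @param max_combinations Safety cap on the enumeration size.
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' mannwhitney_exact(c(53.4, 55.3, 56.3), c(55.0, 57.0, 61.4, 63.6))  # 8/35
mannwhitney_exact <- function(x, y, tail_method = c("doubled", "symmetric"),
                              max_combinations = 5e5) {
  tail_method <- match.arg(tail_method)
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty", class = "cscore_domain_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("values must be finite", class = "cscore_domain_error")
  }
  if (length(intersect(x, y)) > 0) {
    abort("tied values across groups: exact enumeration requires distinct values",
          class = "cscore_domain_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (choose(n, n1) > max_combinations) {
    abort("sample too large for exact enumeration",
          class = "cscore_domain_error")
  }
  pooled_ranks <- rank(c(x, y))
  # U = #(x_i > y_j) = R1 - n1(n1+1)/2 where R1 is the rank sum of group 1
  u_obs <- sum(pooled_ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- combn(n, n1)  # each column: the ranks group 1 could hold
  u_null <- colSums(subsets) - n1 * (n1 + 1) / 2
  m <- length(u_null)
  if (tail_method == "doubled") {
    p <- 2 * min(sum(u_null <= u_obs), sum(u_null >= u_obs)) / m
  } else {
    mu <- n1 * n2 / 2
    p <- sum(abs(u_null - mu) >= abs(u_obs - mu)) / m
  }
  min(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with monotonicity enforcement, in the
#' input order. Thin validated wrapper around [stats::p.adjust()]; used by
#' the synthetic generator to convert per-contrast z-test p-values into FDRs.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]", class = "cscore_domain_error")
  }
  p.adjust(p, method = "BH")
}
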