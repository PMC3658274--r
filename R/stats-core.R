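## Shared statistical primitives used by every downstream stage:
## upper-tail hypergeometric overlap tests, one-sided Fisher enrichment,
## Benjamini-Hochberg FDR, Pearson correlation with explicit degenerate-input
## handling, and permutation p-values with the add-one convention.

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `overlap` common elements between two
#' sets of sizes `size_a` and `size_b` drawn without replacement from a
#' universe of `universe` elements, i.e. `P(X >= overlap)` for
#' `X ~ Hypergeometric(universe, size_a, size_b)`. This is the one-sided
#' enrichment test used for gene-set overlaps between transcriptional
#' modules.
#'
#' All arguments are vectorized and recycled.
#'
#' @param overlap Observed overlap count(s).
#' @param size_a,size_b Sizes of the two sets.
#' @param universe Size of the shared universe (> 0).
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_overlap_p(0, 10, 10, 100)  # 1
#' hypergeom_overlap_p(2, 2, 2, 4)      # 1/6
#' @export
hypergeom_overlap_p <- function(overlap, size_a, size_b, universe) {
  if (length(overlap) == 0L) return(numeric(0))
  n <- max(length(overlap), length(size_a), length(size_b), length(universe))
  overlap <- rep_len(overlap, n)
  size_a <- rep_len(size_a, n)
  size_b <- rep_len(size_b, n)
  universe <- rep_len(universe, n)
  if (any(universe <= 0)) {
    stop("`universe` must be a positive count")
  }
  if (any(size_a < 0 | size_b < 0 | size_a > universe | size_b > universe)) {
    stop("set sizes must lie in [0, universe]")
  }
  lo <- pmax(0, size_a + size_b - universe)
  hi <- pmin(size_a, size_b)
  if (any(overlap < lo | overlap > hi)) {
    stop("`overlap` outside the feasible range [max(0, a+b-N), min(a, b)]")
  }
  stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                lower.tail = FALSE)
}

#' One-sided ("greater") Fisher exact test for a 2x2 table
#'
#' Exact one-sided enrichment p-value for the table
#' `(a, b; c, d)` = (in-set & annotated, in-set & not, out & annotated,
#' out & not). Identical to [hypergeom_overlap_p()] on the equivalent
#' parametrization: overlap `a` between a set of size `a + b` and an
#' annotation of size `a + c` in a universe of `a + b + c + d`.
#'
#' @param a,b,c,d Non-negative integer counts; vectorized.
#' @return One-sided p-value(s) for over-representation.
#' @examples
#' fisher_exact_greater(2, 0, 0, 2)  # 1/6
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  total <- a + b + c + d
  if (any(total == 0)) stop("table total must be positive")
  hypergeom_overlap_p(a, a + b, a + c, total)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector. Returned
#' q-values are order-preserving under permutation of the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with explicit degenerate-input errors
#'
#' Standard Pearson correlation; unlike [stats::cor()] it refuses constant
#' vectors (undefined correlation) instead of returning `NA`, so callers
#' must decide the fallback.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Permutation p-value with the add-one convention
#'
#' `(1 + #{null >= observed}) / (1 + n_null)`. The add-one rule guarantees a
#' strictly positive p-value, so the minimum attainable value with 1000
#' permutations is exactly 1/1001.
#'
#' @param observed Observed test statistic (larger = more extreme).
#' @param null_samples Non-empty numeric vector of null statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null_samples) {
  if (length(null_samples) == 0L) stop("`null_samples` must be non-empty")
  if (!is.finite(observed)) stop("`observed` must be finite")
  (1 + sum(null_samples >= observed)) / (1 + length(null_samples))
}
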