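#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Computes the Pearson statistic N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with
#' df = 1 and its upper-tail p-value. No continuity correction is applied by
#' default: the mismatch-class and stem-loop-retention comparisons in this
#' analysis use the uncorrected Pearson statistic.
#'
#' @param a,b,c,d cell counts, row-major (row 1 = group/category 1); `a`
#'   may instead be a 2x2 matrix.
#' @param continuity apply the Yates correction (default FALSE).
#' @return list: `statistic`, `df`, `p_value`, `table`.
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL, continuity = FALSE) {
  tab <- .as_table2x2(a, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared undefined: zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value), table = tab)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with margins fixed. The default two-sided rule
#' is the point-probability rule: sum the probabilities of all tables (with
#' the same margins) whose point probability does not exceed that of the
#' observed table. `method = "central"` doubles the smaller one-sided tail
#' instead (capped at 1).
#'
#' @inheritParams chi2_2x2
#' @param method "point" (default) or "central".
#' @return list: `p_value`, `odds_ratio` (conditional MLE), `table`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             method = c("point", "central")) {
  method <- match.arg(method)
  tab <- .as_table2x2(a, b, c, d)
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  p <- ht$p.value
  if (method == "central") {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1]); x <- tab[1, 1]
    lower <- stats::phyper(x, m, n2, k)
    upper <- stats::phyper(x - 1, m, n2, k, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  }
  list(p_value = unname(p), odds_ratio = unname(ht$estimate), table = tab)
}

#' Retention statistic for a filtering step
#'
#' Compares the composition of a retained site set (overlapping a reference
#' set vs not) against the full pre-filter set with a chi-squared test on
#' the 2x2 table [retained_overlap, retained_nonoverlap; prefilter_overlap,
#' prefilter_nonoverlap]. Note the rows overlap (the retained set is a
#' subset of the pre-filter set); the construction deliberately mirrors the
#' published computation and is labeled as such in the result.
#'
#' @param retained_overlap,retained_nonoverlap counts in the retained set.
#' @param prefilter_overlap,prefilter_nonoverlap counts in the full
#'   pre-filter set (componentwise >= the retained counts).
#' @param continuity passed to [chi2_2x2()].
#' @return list as [chi2_2x2()] plus `note` documenting the overlapping-rows
#'   construction and `fold_reduction` (prefilter total / retained total).
#' @export
retention_test <- function(retained_overlap, retained_nonoverlap,
                           prefilter_overlap, prefilter_nonoverlap,
                           continuity = FALSE) {
  if (retained_overlap > prefilter_overlap ||
      retained_nonoverlap > prefilter_nonoverlap) {
    stop("retained counts must not exceed pre-filter counts")
  }
  res <- chi2_2x2(retained_overlap, retained_nonoverlap,
                  prefilter_overlap, prefilter_nonoverlap,
                  continuity = continuity)
  res$note <- "rows overlap: retained set is a subset of the pre-filter set"
  res$fold_reduction <- (prefilter_overlap + prefilter_nonoverlap) /
    (retained_overlap + retained_nonoverlap)
  res
}

#' Overlap between two site sets
#'
#' @param a,b character vectors of site keys (any consistent convention),
#'   or `site_set` data.frames (their `key` column is used).
#' @return list: `n_shared`, `n_a_only`, `n_b_only`, `shared` (the keys).
#' @export
overlap_sites <- function(a, b) {
  if (is.data.frame(a)) a <- a$key
  if (is.data.frame(b)) b <- b$key
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  list(n_shared = length(shared),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)),
       shared = shared)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-zero variance.
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

.as_table2x2 <- function(a, b, c, d) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers")
  }
  tab
}
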