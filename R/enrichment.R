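#' Odds ratio of a 2x2 contingency table
#'
#' For group membership i crossed with unit membership j,
#' \deqn{OR = (N_{ij}/N_{i\bar j}) / (N_{\bar i j}/N_{\bar i \bar j}).}
#' Edge conventions: \eqn{N_{ij} = 0} gives 0; \eqn{N_{\bar i j} = 0} with
#' \eqn{N_{ij} > 0} gives +Inf; 0/0 branches are undefined (NA).
#'
#' @param table 2x2 matrix or length-4 vector \code{c(N_ij, N_inotj, N_notij,
#'   N_notinotj)} (row-major: in-group first row).
#' @return A single numeric odds ratio (possibly 0, Inf or NA).
#' @export
odds_ratio <- function(table) {
  v <- as.numeric(table)
  stopifnot(length(v) == 4L, all(v >= 0))
  a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  if (a == 0 && c_ == 0) return(NA_real_)
  if (a == 0) return(0)
  if (c_ == 0) return(Inf)
  if (b == 0 && d == 0) return(NA_real_)
  if (b == 0) return(Inf)
  if (d == 0) return(0)
  (a / b) / (c_ / d)
}

#' One-sided Fisher exact test (enrichment direction)
#'
#' Exact hypergeometric tail probability \eqn{P[X \ge N_{ij}]} with all
#' margins fixed, i.e. the single-sided ("greater") Fisher exact test used
#' for overrepresentation. Computed from the hypergeometric distribution
#' function; vectorized over tables.
#'
#' @param a,b,c_,d Cell counts as in \code{\link{odds_ratio}} (vectors), or
#'   pass a single 2x2 matrix/length-4 vector as \code{a}.
#' @return Numeric vector of one-sided p-values.
#' @export
fisher_one_sided <- function(a, b = NULL, c_ = NULL, d = NULL) {
  if (is.null(b)) {
    v <- as.numeric(a)
    stopifnot(length(v) == 4L)
    a <- v[1]; b <- v[2]; c_ <- v[3]; d <- v[4]
  }
  stats::phyper(a - 1, m = a + c_, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control; adjusted values are monotone in the
#' sorted p-values and capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted values in the input order.
#' @export
fdr_bh <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

## distribution of subset sums of integer weights w (all 2^n subsets),
## as counts over sums 0..sum(w); polynomial multiplication
.subset_sum_counts <- function(w) {
  total <- sum(w)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), counts[seq_len(total + 1L - wi)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided by default. Zero differences are dropped and tied absolute
#' differences receive midranks. For n <= 25 nonzero differences the exact
#' sign-flip null distribution of the rank sum is used (computed by
#' convolution over the doubled midranks, so ties are handled exactly);
#' above that, the normal approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exact_max Largest n for the exact branch (default 25).
#' @return p-value (1 when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided",
                                 exact_max = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  if (n > exact_max) {
    return(suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               alternative = alternative,
                                               exact = FALSE,
                                               correct = TRUE)$p.value))
  }
  r2 <- as.integer(round(2 * rank(abs(d))))      # doubled midranks: integers
  counts <- .subset_sum_counts(r2)
  t_obs <- sum(r2[d > 0])
  lower <- sum(counts[seq_len(t_obs + 1L)]) / 2^n
  upper <- sum(counts[seq.int(t_obs + 1L, length(counts))]) / 2^n
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         greater = upper,
         less = lower)
}

## counts of k-subsets of integer weights w by subset sum
.k_subset_sum_counts <- function(w, k) {
  total <- sum(w)
  counts <- matrix(0, k + 1L, total + 1L)
  counts[1L, 1L] <- 1
  for (wi in w) {
    for (kk in rev(seq_len(k))) {
      shifted <- c(numeric(wi), counts[kk, seq_len(total + 1L - wi)])
      counts[kk + 1L, ] <- counts[kk + 1L, ] + shifted
    }
  }
  counts[k + 1L, ]
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Two-sided by default; ties get midranks. For samples with n, m <= 12 the
#' exact permutation distribution of the first-sample rank sum is used
#' (convolution over doubled pooled midranks, exact under ties); larger
#' samples use the normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exact_max Largest per-sample size for the exact branch (default 12).
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided",
                              exact_max = 12L) {
  n <- length(x); m <- length(y)
  if (n > exact_max || m > exact_max) {
    return(suppressWarnings(stats::wilcox.test(x, y,
                                               alternative = alternative,
                                               exact = FALSE,
                                               correct = TRUE)$p.value))
  }
  r2 <- as.integer(round(2 * rank(c(x, y))))
  counts <- .k_subset_sum_counts(r2, n)
  total_subsets <- choose(n + m, n)
  w_obs <- sum(r2[seq_len(n)])
  lower <- sum(counts[seq_len(w_obs + 1L)]) / total_subsets
  upper <- sum(counts[seq.int(w_obs + 1L, length(counts))]) / total_subsets
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         greater = upper,
         less = lower)
}

#' Group-in-unit enrichment table
#'
#' For every (group, unit) combination, builds the 2x2 contingency table of
#' group membership against unit membership over all pairs, and reports the
#' odds ratio, the single-sided (enrichment) Fisher exact p-value and the
#' BH-FDR across the whole family of tests. Units with no members are
#' flagged \code{"empty_unit"}.
#'
#' @param assignments Vector of unit ids, one per pair.
#' @param groups Vector of group labels, one per pair.
#' @param units,group_levels Optional explicit level sets (defaults: observed
#'   sorted unique values).
#' @return data.frame \code{group, unit, n_in, odds_ratio, p, fdr, flag}.
#' @export
group_unit_enrichment <- function(assignments, groups,
                                  units = sort(unique(assignments)),
                                  group_levels = sort(unique(groups))) {
  stopifnot(length(assignments) == length(groups))
  n <- length(assignments)
  res <- expand.grid(group = group_levels, unit = units,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$n_in <- NA_integer_; res$odds_ratio <- NA_real_
  res$p <- NA_real_; res$flag <- ""
  for (k in seq_len(nrow(res))) {
    gi <- groups == res$group[k]
    uj <- assignments == res$unit[k]
    a <- sum(gi & uj); b <- sum(gi & !uj)
    c_ <- sum(!gi & uj); d <- sum(!gi & !uj)
    res$n_in[k] <- a
    res$odds_ratio[k] <- odds_ratio(c(a, b, c_, d))
    res$p[k] <- fisher_one_sided(a, b, c_, d)
    if (a + c_ == 0L) res$flag[k] <- "empty_unit"
  }
  res$fdr <- fdr_bh(res$p)
  res[, c("group", "unit", "n_in", "odds_ratio", "p", "fdr", "flag")]
}

#' Pairwise rank-sum comparison of a metric across groups
#'
#' Wilcoxon rank-sum tests between every pair of groups on a numeric column
#' (e.g. mean conservation score across nRDD groups), BH-adjusted.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return data.frame \code{group1, group2, p, fdr}.
#' @export
compare_groups <- function(values, groups) {
  lev <- sort(unique(groups))
  cmb <- utils::combn(lev, 2)
  p <- apply(cmb, 2, function(g) {
    wilcoxon_rank_sum(values[groups == g[1]], values[groups == g[2]])
  })
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], p = p, fdr = fdr_bh(p),
             stringsAsFactors = FALSE)
}
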