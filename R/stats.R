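#' One-sided two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the signed difference between the two empirical
#' distribution functions, evaluated over all pooled data points. With
#' `alternative = "a_below_b"` the statistic is `sup_x (F_a(x) - F_b(x))`,
#' which is large when sample `a` is stochastically smaller (shifted to
#' lower values) than sample `b`; `"a_above_b"` is the mirror image. The
#' statistic, not a p-value, is the reported quantity.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative direction of the comparison.
#' @return the one-sided D statistic in `[0, 1]`.
#' @export
ks_statistic <- function(a, b, alternative = c("a_below_b", "a_above_b")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  d <- if (alternative == "a_below_b") max(fa - fb) else max(fb - fa)
  max(d, 0)
}

#' Two-proportion comparison table
#'
#' Summarizes a 2x2 table of (stratum x divergent/non-divergent) counts:
#' per-stratum proportions, their difference, and the uncorrected
#' chi-square statistic with p-value (delegated to [stats::chisq.test()]).
#'
#' @param counts a 2x2 matrix or table; rows are strata, column 1 holds
#'   "success" (e.g. divergent) counts, column 2 the rest.
#' @return a list with `prop_1`, `prop_2`, `difference`, `chisq`,
#'   `p_value`, `flags`.
#' @export
proportion_report <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  flags <- character(0)
  n1 <- sum(counts[1, ]); n2 <- sum(counts[2, ])
  if (n1 == 0 || n2 == 0 || any(colSums(counts) == 0)) {
    flags <- c(flags, "zero_margin")
    chisq <- NA_real_; pval <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    chisq <- unname(ct$statistic); pval <- unname(ct$p.value)
  }
  p1 <- if (n1 > 0) counts[1, 1] / n1 else NA_real_
  p2 <- if (n2 > 0) counts[2, 1] / n2 else NA_real_
  list(prop_1 = p1, prop_2 = p2, difference = p1 - p2,
       chisq = chisq, p_value = pval, flags = flags)
}
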