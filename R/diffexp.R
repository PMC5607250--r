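#' Reads-per-million normalization
#'
#' `tpm(count, total) = 1e6 * count / total`, with the library's total clean
#' (valid) read count as denominator. No zero substitution is applied here.
#'
#' @param count Non-negative read count(s).
#' @param total Positive library total.
#' @return Normalized expression (reads per million).
#' @export
#' @examples
#' tpm(463, 7997385)
tpm <- function(count, total) {
  stopifnot(all(total > 0))
  1e6 * count / total
}

#' Exact test for a count observed in two libraries
#'
#' The conditional distribution of the second library's count `y` given the
#' first library's count `x`, for library sizes `N1` and `N2`, is
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.}
#' The lower tail is \eqn{C = \sum_{k \le y} p(k|x)}, the upper tail
#' \eqn{D = \sum_{k \ge y} p(k|x)}, and the two-sided p-value is
#' `min(1, 2 * min(C, D))`. All terms are computed in log space with a
#' deterministic ascending summation.
#'
#' @param x,y Non-negative counts in the two libraries.
#' @param N1,N2 Positive library totals.
#' @return A list with `point` (the mass `p(y|x)`), `lower` (C), `upper`
#'   (D), and `two_sided`.
#' @export
#' @examples
#' ac_pvalue(5, 1, 1e6, 1e6)$point # 6!/(5! 1! 2^7)
ac_pvalue <- function(x, y, N1, N2) {
  stopifnot(length(x) == 1, length(y) == 1)
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  r <- N2 / N1
  logp <- function(k) {
    k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(r)
  }
  ks <- 0:y
  point <- exp(logp(y))
  lower <- sum(exp(logp(ks)))
  lower <- min(1, lower)
  upper <- if (y == 0) 1 else max(0, min(1, 1 - sum(exp(logp(0:(y - 1))))))
  list(point = point, lower = lower, upper = upper,
       two_sided = min(1, 2 * min(lower, upper)))
}

# Vectorized two-sided exact p-values.
#' @noRd
ac_test <- function(x, y, N1, N2) {
  vapply(seq_along(x), function(i) ac_pvalue(x[i], y[i], N1, N2)$two_sided,
         numeric(1))
}

#' Companion 2x2 tests for a two-library count
#'
#' Two-sided Fisher exact and continuity-corrected chi-square tests on the
#' table `[[x, N1 - x], [y, N2 - y]]`.
#'
#' @inheritParams ac_pvalue
#' @return List with `fisher_p` and `chi2_p`.
#' @export
test_2x2 <- function(x, y, N1, N2) {
  m <- matrix(c(x, N1 - x, y, N2 - y), nrow = 2, byrow = TRUE)
  if (x + y == 0) return(list(fisher_p = 1, chi2_p = 1))
  f <- stats::fisher.test(m)$p.value
  ch <- tryCatch(
    suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value),
    error = function(e) NA_real_)
  if (is.nan(ch)) ch <- 1
  list(fisher_p = min(1, f), chi2_p = ch)
}

#' Thresholds for differential-expression calling
#'
#' A miRNA is differentially expressed when its summed raw reads exceed
#' `min_total_reads`, its exact-test p-value is below `alpha`, and its
#' absolute log2 fold change is at least `min_abs_log2fc`. Records below
#' `low_expression_floor` reads-per-million in both libraries are removed
#' before testing; a zero normalized expression is substituted with
#' `zero_substitute` before the fold change is formed.
#'
#' @param min_total_reads Summed raw-read threshold (strictly greater).
#' @param alpha Significance level.
#' @param min_abs_log2fc Absolute log2 fold-change threshold.
#' @param low_expression_floor RPM floor below which (in both libraries) a
#'   record is removed.
#' @param zero_substitute Value substituted for a zero RPM.
#' @return List of class `"de_thresholds"`.
#' @export
de_thresholds <- function(min_total_reads = 10, alpha = 0.05,
                          min_abs_log2fc = 1.5, low_expression_floor = 1,
                          zero_substitute = 0.01) {
  stopifnot(min_total_reads > 0, alpha > 0, min_abs_log2fc > 0,
            low_expression_floor > 0, zero_substitute > 0)
  structure(as.list(environment()), class = "de_thresholds")
}

#' Differential-expression table for two pooled libraries
#'
#' Applies, in order: reads-per-million normalization against the two
#' libraries' total clean reads; removal of records below the low-expression
#' floor in both libraries; substitution of zero normalized values before
#' the fold change `log2(L/E)`; the exact test plus Fisher and chi-square
#' companions; and the DE/specific flags. A Benjamini-Hochberg column on the
#' exact-test p-values is emitted for reference but never gates any flag.
#'
#' @param counts Data frame with `id`, `x` (raw count in E) and `y` (raw
#'   count in L); alternatively a tag table whose `sequence` is used as id
#'   with `count_E`/`count_L` counts.
#' @param totals Named or positional pair `(N1, N2)` of total clean reads.
#' @param th A [de_thresholds()] object.
#' @return Data frame with `id`, `x`, `y`, `tpm_E`, `tpm_L`, `log2fc`,
#'   `p_ac`, `p_fisher`, `p_chi2`, `p_ac_bh`, and logical flags
#'   `removed_low`, `de`, `specific_E`, `specific_L`. Removed records keep
#'   `NA` p-values.
#' @export
de_table <- function(counts, totals, th = de_thresholds()) {
  if (any(totals <= 0)) stop("library totals must be positive")
  d <- counts
  if (is.null(d$id) && !is.null(d$sequence)) {
    d <- data.frame(id = d$sequence, x = d$count_E, y = d$count_L,
                    stringsAsFactors = FALSE)
  }
  N1 <- as.numeric(totals[[1]]); N2 <- as.numeric(totals[[2]])
  d$tpm_E <- tpm(d$x, N1)
  d$tpm_L <- tpm(d$y, N2)
  d$removed_low <- d$tpm_E < th$low_expression_floor &
    d$tpm_L < th$low_expression_floor
  eE <- ifelse(d$tpm_E == 0, th$zero_substitute, d$tpm_E)
  eL <- ifelse(d$tpm_L == 0, th$zero_substitute, d$tpm_L)
  d$log2fc <- log2(eL / eE)
  d$p_ac <- NA_real_; d$p_fisher <- NA_real_; d$p_chi2 <- NA_real_
  test <- which(!d$removed_low)
  for (i in test) {
    d$p_ac[i] <- ac_pvalue(d$x[i], d$y[i], N1, N2)$two_sided
    t2 <- test_2x2(d$x[i], d$y[i], N1, N2)
    d$p_fisher[i] <- t2$fisher_p
    d$p_chi2[i] <- t2$chi2_p
  }
  d$p_ac_bh <- NA_real_
  d$p_ac_bh[test] <- stats::p.adjust(d$p_ac[test], method = "BH")
  d$de <- !d$removed_low & (d$x + d$y) > th$min_total_reads &
    !is.na(d$p_ac) & d$p_ac < th$alpha & abs(d$log2fc) >= th$min_abs_log2fc
  d$specific_E <- d$y == 0 & d$x > th$min_total_reads
  d$specific_L <- d$x == 0 & d$y > th$min_total_reads
  d
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_A - Ct_ref_A) - (Ct_target_B - Ct_ref_B)`, where B is
#' the calibrator condition and the reference is a housekeeping RNA (e.g.
#' U6); the relative expression of condition A is `2^-ddCt`.
#'
#' @param ct_target_a,ct_ref_a Threshold cycles in the test condition.
#' @param ct_target_b,ct_ref_b Threshold cycles in the calibrator.
#' @return Relative expression `2^-ddCt`.
#' @export
#' @examples
#' ddct(20, 15, 22, 15) # 4-fold higher in the calibrator
ddct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  stopifnot(all(c(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) > 0))
  dd <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-dd)
}

#' Empirical type-I error of the exact test under the null
#'
#' Simulates `n_genes` features with equal expected counts in two libraries
#' of the given sizes (Poisson sampling) and reports the fraction of
#' two-sided exact-test p-values below `alpha`. Uses the current RNG state.
#'
#' @param n_genes Number of null features.
#' @param mean_count Expected count per feature per library.
#' @param N1,N2 Library totals.
#' @param alpha Significance level.
#' @return Fraction of null features rejected.
#' @export
null_type1 <- function(n_genes = 100, mean_count = 100, N1 = 1e6, N2 = 1e6,
                       alpha = 0.05) {
  x <- stats::rpois(n_genes, mean_count)
  y <- stats::rpois(n_genes, mean_count * N2 / N1)
  mean(ac_test(x, y, N1, N2) < alpha)
}
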