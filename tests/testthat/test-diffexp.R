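test_that("reads-per-million normalization is the exact formula", {
  expect_equal(tpm(463, 7997385), 1e6 * 463 / 7997385)
  expect_equal(tpm(463, 7997385), 57.8939, tolerance = 1e-4)
  expect_equal(tpm(0, 123), 0)
  expect_equal(tpm(123, 123), 1e6)
})

test_that("the exact test matches closed-form values at equal totals", {
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6)$point, 0.5)
  # p(1|5) = 6! / (5! 1! 2^7)
  expect_equal(ac_pvalue(5, 1, 1e6, 1e6)$point, 0.046875)
  expect_equal(ac_pvalue(5, 1, 123, 123)$point, 720 / (120 * 1 * 2^7))
})

test_that("the conditional distribution is proper and symmetric", {
  for (x in c(0, 1, 3, 10)) {
    for (r in c(0.5, 1, 2)) {
      N1 <- 1e6; N2 <- r * 1e6
      total <- sum(vapply(0:400, function(k) ac_pvalue(x, k, N1, N2)$point,
                          numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
  # swapping counts and totals: exact equality at equal totals, and the
  # scaling identity p(y|x; N1, N2) = (N1/N2) p(x|y; N2, N1) in general
  for (x in 0:19) for (y in 0:19) {
    expect_equal(ac_pvalue(x, y, 1e6, 1e6)$point,
                 ac_pvalue(y, x, 1e6, 1e6)$point, tolerance = 1e-12)
  }
  N1 <- 2e6; N2 <- 5e5
  for (x in c(0, 3, 9)) for (y in c(0, 5, 12)) {
    expect_equal(ac_pvalue(x, y, N1, N2)$point,
                 (N1 / N2) * ac_pvalue(y, x, N2, N1)$point,
                 tolerance = 1e-12)
  }
})

test_that("tails and the two-sided rule behave", {
  r <- ac_pvalue(3, 50, 1e6, 1e6)
  expect_true(r$lower > 0.999 && r$upper < 1e-6)
  expect_equal(r$two_sided, min(1, 2 * min(r$lower, r$upper)))
  expect_equal(ac_pvalue(5, 5, 1e6, 1e6)$two_sided, 1)
  expect_error(ac_pvalue(-1, 0, 10, 10), "non-negative")
})

test_that("Fisher and chi-square companions are sane", {
  t0 <- test_2x2(20, 20, 1e6, 1e6)
  expect_equal(t0$fisher_p, 1.0)
  t1 <- test_2x2(50, 0, 1e6, 1e6)
  expect_lt(t1$fisher_p, 1e-10)
  expect_lt(t1$chi2_p, 1e-10)
  set.seed(30)
  for (i in 1:50) {
    x <- rpois(1, 50); y <- rpois(1, 50)
    tt <- test_2x2(x, y, 1e6, 2e6)
    expect_true(tt$fisher_p >= 0 && tt$fisher_p <= 1)
    expect_true(tt$chi2_p >= 0 && tt$chi2_p <= 1)
  }
})

test_that("exact and chi-square p-values agree for large counts", {
  for (y in c(110, 130, 150, 180)) {
    pa <- ac_pvalue(100, y, 1e6, 1e6)$two_sided
    pc <- test_2x2(100, y, 1e6, 1e6)$chi2_p
    expect_lt(abs(log10(pa) - log10(pc)), 1, label = paste("y =", y))
  }
})

test_that("the DE table applies floor, substitution and flags in order", {
  counts <- data.frame(
    id = c("low", "zeroL", "big", "paper"),
    x = c(1, 20, 100, 6),
    y = c(1, 0, 3200, 463))
  # the paper-style record uses the two libraries' valid-read totals
  de <- de_table(counts, totals = c(17306229, 7997385))
  expect_true(de$removed_low[de$id == "low"])      # < 1 RPM in both
  expect_true(is.na(de$p_ac[de$id == "low"]))
  z <- de[de$id == "zeroL", ]
  expect_equal(z$tpm_L, 0)
  expect_equal(z$log2fc, log2(0.01 / z$tpm_E))     # zero -> 0.01 before FC
  expect_true(z$specific_E)
  expect_false(z$specific_L)
  p <- de[de$id == "paper", ]
  expect_false(p$removed_low)
  expect_true(p$de)
  expect_gt(p$log2fc, 0)                           # toward late lactation
  expect_lt(p$p_ac, 1e-10)
  b <- de[de$id == "big", ]
  expect_true(b$de)
  expect_true(all(de$p_ac_bh >= de$p_ac, na.rm = TRUE))
})

test_that("DE flags require evidence, significance and fold change", {
  th <- de_thresholds()
  # significant but below the fold-change threshold
  d1 <- de_table(data.frame(id = "a", x = 1000, y = 1500),
                 totals = c(1e6, 1e6), th)
  expect_lt(d1$p_ac, 0.05)
  expect_false(d1$de)
  # too few reads
  d2 <- de_table(data.frame(id = "b", x = 5, y = 5), totals = c(1e5, 1e5), th)
  expect_false(d2$de)
})

test_that("power: planted 3-log2 changes are recovered", {
  set.seed(31)
  flagged <- 0L; n <- 100L
  for (i in seq_len(n)) {
    x <- rpois(1, 200 * 2^(-1.5))
    y <- rpois(1, 200 * 2^(1.5))
    d <- de_table(data.frame(id = "g", x = x, y = y), totals = c(1e6, 1e6))
    flagged <- flagged + d$de
  }
  expect_gte(flagged / n, 0.95)
})

test_that("null type-I error of the exact test is near nominal", {
  set.seed(32)
  rate <- null_type1(n_genes = 2000, mean_count = 100)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("2^-ddCt arithmetic", {
  expect_equal(ddct(20, 15, 20, 15), 1)
  expect_equal(ddct(19, 15, 20, 15), 2)          # ddCt = -1
  expect_equal(ddct(20 + log2(10), 20, 20, 20), 0.1, tolerance = 1e-4)
})
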