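test_that("frequency estimates apply the doubling adjustment and rounding", {
  e424 <- estimate_frequency(tetrad_counts("424-GC1", 147848, 79))
  expect_equal(e424$raw_frequency, 79 / 147848)
  expect_equal(e424$adjusted_frequency, 2 * 79 / 147848)
  expect_equal(format_sci3(e424$adjusted_frequency), "1.07E-03")
  expect_equal(e424$meioses_per_conversion, 936)

  e1659 <- estimate_frequency(tetrad_counts("1659-GC1", 149965, 13))
  expect_equal(e1659$meioses_per_conversion, 5768)

  # half-up rounding at an exact .5: 155280 / 32 = 4852.5
  e1369 <- estimate_frequency(tetrad_counts("1369-GC1", 155280, 16))
  expect_equal(e1369$meioses_per_conversion, 4853)

  ez <- estimate_frequency(tetrad_counts("ctl", 45000, 0))
  expect_equal(ez$adjusted_frequency, 0)
  expect_true(is.na(ez$meioses_per_conversion))

  expect_error(estimate_frequency(tetrad_counts("x", 0, 0)), "positive")
  expect_warning(estimate_frequency(tetrad_counts("x", 50, 50)),
                 "exceeds 1")
})

test_that("frequency estimation is scale-consistent", {
  base <- estimate_frequency(tetrad_counts("x", 1000, 3))
  for (k in c(2, 7, 100)) {
    scaled <- estimate_frequency(tetrad_counts("x", 1000 * k, 3 * k))
    expect_equal(scaled$raw_frequency, base$raw_frequency)
    expect_equal(scaled$adjusted_frequency, base$adjusted_frequency)
  }
})

test_that("pooling sums counts before estimating", {
  pooled <- pool_counts(gc_counts())
  expect_equal(pooled$n_31, 186)
  expect_equal(pooled$n_tetrads, 1054024)
  expect_equal(format_sci3(pooled$adjusted_frequency), "3.53E-04")
  expect_equal(pooled$meioses_per_conversion, 2833)

  one <- gc_counts()[3, ]
  expect_equal(pool_counts(one)$adjusted_frequency,
               estimate_frequency(one)$adjusted_frequency)

  # equal per-locus frequencies pool to the common value
  two <- rbind(tetrad_counts("a", 1000, 2), tetrad_counts("b", 5000, 10))
  expect_equal(pool_counts(two)$raw_frequency, 2 / 1000)

  expect_error(pool_counts(gc_counts()[0, ]), "empty")
})

test_that("G-test matches independent oracles on random 2x2 tables", {
  tables <- random_tables(300, seed = 42)
  for (tb in tables) {
    res <- g_test_independence(tb["k1"], tb["n1"], tb["k2"], tb["n2"])
    g_ref <- g_oracle(tb["k1"], tb["n1"], tb["k2"], tb["n2"])
    # relative agreement where G is meaningfully nonzero; near zero both
    # routes are dominated by cancellation, so compare absolutely
    if (g_ref >= 1) {
      expect_lt(abs(res$g_statistic - g_ref) / g_ref, 1e-9)
    } else {
      expect_lt(abs(res$g_statistic - g_ref), 1e-9)
    }
    expect_lt(abs(res$p_value - p_oracle_df1(res$g_statistic)), 1e-6)
  }
})

test_that("G-test is symmetric and handles degenerate tables", {
  a <- g_test_independence(17, 148886, 79, 147848)
  b <- g_test_independence(79, 147848, 17, 148886)
  expect_equal(a$g_statistic, b$g_statistic)
  # swapping the success/failure columns leaves G unchanged
  d <- g_test_independence(148886 - 17, 148886, 147848 - 79, 147848)
  expect_equal(a$g_statistic, d$g_statistic, tolerance = 1e-9)

  ident <- g_test_independence(5, 100, 5, 100)
  expect_equal(ident$g_statistic, 0)
  expect_equal(ident$p_value, 1)

  degen <- g_test_independence(0, 45000, 0, 45000)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  # p monotone decreasing in G at fixed df
  gs <- c(0.1, 1, 5, 20, 60)
  ps <- stats::pchisq(gs, 1, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  expect_error(g_test_independence(5, 0, 1, 10), "positive")
  expect_error(g_test_independence(11, 10, 1, 10), "0 <= k <= n")
})

test_that("pairwise matrix reproduces the published locus comparisons", {
  pw <- pairwise_g_matrix(gc_counts(include_intra = TRUE))
  p <- pw$p_value
  expect_true(isSymmetric(p))
  expect_true(all(is.na(diag(p))))
  expect_equal(format_p_printed(p["567-GC1", "3282-GC1"]), "0.97")
  expect_equal(format_p_printed(p["1369-GC1", "1369-GC2"]), "0.94")
  expect_equal(format_p_printed(p["3411-GC1", "1659-GC1"]), "0.01")
  # 424-GC1 vs 1659-GC1: G ~ 53.5, p on the order of 1e-13
  expect_equal(pw$g_statistic["424-GC1", "1659-GC1"],
               g_oracle(79, 147848, 13, 149965), tolerance = 1e-9)
  expect_lt(p["424-GC1", "1659-GC1"], 1e-12)
  expect_gt(p["424-GC1", "1659-GC1"], 1e-14)

  # permuting input order permutes rows/columns consistently
  shuf <- gc_counts(include_intra = TRUE)[c(3, 1, 8, 2, 5, 4, 7, 6), ]
  pw2 <- pairwise_g_matrix(shuf)
  expect_equal(pw2$p_value[rownames(p), colnames(p)], p)
})

test_that("control comparisons reconstruct the published false-positive test", {
  ctl <- control_counts()[1, ]
  ref <- gc_counts()[gc_counts()$label == "1659-GC1", ]
  res <- control_comparison(ctl, ref)
  expect_equal(res$g_statistic, 6.8231, tolerance = 1e-4)
  expect_equal(res$p_value, 0.008998, tolerance = 1e-4)
  expect_match(res$report, "0/45000")

  # the same control against the pooled total gives a much smaller p:
  # the published 0.008998 corresponds to the single-locus comparison
  pooled <- tetrad_counts("total", 1054024, 186)
  res_pool <- control_comparison(ctl, pooled)
  expect_lt(res_pool$p_value, 1e-4)
  expect_gt(res_pool$p_value, 1e-5)

  same <- control_comparison(ctl, tetrad_counts("c2", 45000, 0))
  expect_equal(same$p_value, 1)
})

test_that("SNP-position regression is flat on the packaged alleles", {
  alle <- nftl_alleles(sequenced_only = TRUE)
  cnt <- gc_counts(include_intra = TRUE)
  merged <- merge(alle, cnt, by.x = "allele_name", by.y = "label")
  expect_equal(nrow(merged), 8)
  est <- estimate_frequency(tetrad_counts(merged$allele_name,
                                          merged$n_tetrads, merged$n_31))
  reg <- position_regression(merged$snp_position, est$adjusted_frequency)
  expect_equal(round(reg$r_squared, 3), 0.038)
  expect_equal(round(reg$p_value, 3), 0.645)
  expect_equal(reg$n, 8)

  # exactly collinear points (lm warns about the perfect fit)
  col3 <- suppressWarnings(
    position_regression(c(10, 20, 30), c(1e-4, 2e-4, 3e-4)))
  expect_equal(col3$r_squared, 1)

  # constant frequencies: flat fit, no evidence
  flat <- position_regression(c(10, 20, 30), rep(2e-4, 3))
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  expect_error(position_regression(c(5, 5, 5), c(1, 2, 3) * 1e-4),
               "identical")
  expect_error(position_regression(c(1, 2), c(1e-4, 2e-4)), "at least 3")
})
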