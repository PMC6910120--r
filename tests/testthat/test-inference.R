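# Critical thresholds and suprathreshold intervals.

test_that("two-tailed p-values behave as defined", {
  tf <- fake_tfield(c(0, 2 * sqrt(3), -2 * sqrt(3)), df = 2)
  p <- p_from_t(tf)
  expect_equal(p[1], 1)
  expect_equal(p[2], 0.0741799, tolerance = 1e-6)   # Student-t CDF, df = 2
  expect_equal(p[2], p[3])                          # symmetry p(t) = p(-t)
  expect_true(all(p > 0 & p <= 1))
  expect_error(p_from_t(c(1, Inf), df = 3), "non-finite")
})

test_that("uncorrected and Bonferroni thresholds: values, limits, identities", {
  expect_equal(threshold_uncorrected(0.05, 9), 2.262157, tolerance = 1e-5)
  expect_lt(threshold_uncorrected(0.999, 9), 0.002)         # alpha -> 1 limit
  expect_equal(threshold_bonferroni(0.05, 9, 1), threshold_uncorrected(0.05, 9))
  # independently verified quantile (scipy.stats.t.ppf(1 - 0.05/202, 9))
  expect_equal(threshold_bonferroni(0.05, 9, 101), 5.298176, tolerance = 1e-5)
  qs <- vapply(c(1, 2, 10, 101, 500), threshold_bonferroni,
               0, alpha = 0.05, df = 9)
  expect_true(all(diff(qs) > 0))                            # monotone in Q
  expect_error(threshold_uncorrected(1.2, 9), "alpha")
})

test_that("RFT threshold solves the EC equation and obeys its limits", {
  u <- threshold_rft(0.05, 9, 101, 20)
  # root correctness against an in-test re-statement of the EC density
  ec <- pt(u, 9, lower.tail = FALSE) +
    (100 / 20) * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / 9)^(-4)
  expect_lt(abs(ec - 0.025), 1e-5)

  # nearly flat field: approaches the uncorrected value (slow in resels;
  # within 0.01 once resels ~ 1e-4)
  expect_lt(abs(threshold_rft(0.05, 9, 101, 1e6) -
                threshold_uncorrected(0.05, 9)), 0.01)

  # strictly decreasing in fwhm and in df
  by_fwhm <- vapply(c(5, 10, 20, 40, 100), threshold_rft,
                    0, alpha = 0.05, df = 9, Q = 101)
  expect_true(all(diff(by_fwhm) < 0))
  by_df <- vapply(c(5, 9, 15, 30, 60), function(d)
    threshold_rft(0.05, d, 101, 20), 0)
  expect_true(all(diff(by_df) < 0))
})

test_that("BH critical p matches hand enumeration and the brute-force oracle", {
  # hand case: comparisons against (0.0125, 0.025, 0.0375, 0.05)
  expect_equal(fdr_critical_p(c(0.010, 0.020, 0.040, 0.060), 0.05), 0.020)
  # no-discovery and full-discovery cases
  expect_true(is.na(fdr_critical_p(c(0.3, 0.6, 0.9), 0.05)))
  pfull <- c(1e-4, 2e-4, 3e-4)
  expect_equal(fdr_critical_p(pfull, 0.05), 3e-4)

  # property: exact equivalence with exhaustive enumeration on random
  # p-vectors of varying size and signal content
  set.seed(41)
  for (i in 1:300) {
    Q <- sample(3:150, 1)
    p <- switch(1 + i %% 3,
                runif(Q),
                runif(Q)^3,                          # many small p's
                pmin(1, c(runif(Q - 2), 1e-5, 2e-5)))
    expect_identical(fdr_critical_p(p, 0.05), bh_brute_force(p, 0.05))
  }
})

test_that("FDR threshold adapts to the field and signals the undefined case", {
  d <- synthesize_dataset(20, 101, 20, center = 50, sigma = 4, amp = 3,
                          design = "one-sample", seed = 44)
  tf <- one_sample_t(d$sample)
  thr <- threshold_fdr(tf, 0.05)
  expect_false(is.na(thr))
  # the threshold reproduces the BH rejection set: |t| >= thr <=> p <= p*
  p <- p_from_t(tf)
  expect_identical(which(p <= attr(thr, "p_crit")),
                   which(abs(tf$t) >= as.numeric(thr) - 1e-10))

  tf0 <- one_sample_t(generate_noise(10, 101, 20, seed = 45))
  expect_true(is.na(threshold_fdr(tf0, 0.05)))      # typical null field
})

test_that("threshold_set orders thresholds as theory requires", {
  for (s in 1:15) {
    tf <- one_sample_t(generate_noise(8, 101, 10 + 2 * s, seed = 600 + s))
    ts <- threshold_set(tf, 0.05)
    expect_lte(ts$uncorrected, ts$rft)
    expect_lte(ts$rft, ts$bonferroni)    # fwhm >= 10, Q = 101 regime
    expect_identical(ts$fdr_defined, !is.na(ts$fdr))
  }
  # alpha monotonicity
  tf <- one_sample_t(generate_noise(10, 101, 20, seed = 77))
  a5 <- threshold_set(tf, 0.05); a50 <- threshold_set(tf, 0.5)
  expect_lt(a50$uncorrected, a5$uncorrected)
  expect_lt(a50$rft, a5$rft)
  expect_lt(a50$bonferroni, a5$bonferroni)
})

test_that("significant intervals are maximal runs with percent display", {
  tf <- fake_tfield(rep(0.5, 101))
  expect_identical(nrow(significant_intervals(tf, 2)), 0L)

  t <- rep(0, 101); t[96:101] <- 5                   # nodes 95..100, 0-based
  iv <- significant_intervals(fake_tfield(t), 2)
  expect_identical(nrow(iv), 1L)
  expect_identical(iv$start, 95L)
  expect_identical(iv$end, 101L)                     # half-open
  expect_equal(iv$start_pct, 95)
  expect_equal(iv$end_pct, 100)

  t2 <- rep(0, 101); t2[c(3:10, 40:45)] <- -4        # two runs, sign ignored
  iv2 <- significant_intervals(fake_tfield(t2), 2)
  expect_identical(nrow(iv2), 2L)
  expect_true(all(iv2$end > iv2$start))
  expect_true(all(diff(as.vector(rbind(iv2$start, iv2$end))) >= 0))

  # overwhelming SNR pulse: exactly one interval containing node 50
  d <- synthesize_dataset(20, 101, 20, center = 50, sigma = 3, amp = 4,
                          design = "one-sample", seed = 46)
  tf3 <- one_sample_t(d$sample)
  iv3 <- significant_intervals(tf3, threshold_rft(0.05, tf3$df, 101, tf3$fwhm))
  expect_identical(nrow(iv3), 1L)
  expect_true(iv3$start <= 50 && iv3$end > 50)
})
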