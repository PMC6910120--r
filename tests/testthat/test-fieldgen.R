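# Smooth Gaussian noise generator, Gaussian pulse, dataset synthesis.

test_that("generator is reproducible and validates its parameters", {
  a <- generate_noise(5, 31, 12, seed = 99)
  b <- generate_noise(5, 31, 12, seed = 99)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(generate_noise(5, 31, 12, seed = 100))))

  # seeded generation must not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(3)
  set.seed(1); invisible(generate_noise(4, 20, 8, seed = 5)); x2 <- rnorm(3)
  expect_identical(x1, x2)

  expect_error(generate_noise(1, 101, 20), "J")
  expect_error(generate_noise(10, 1, 20), "Q")
  expect_error(generate_noise(10, 101, 0), "fwhm")
  expect_error(generate_noise(10, 101, -3), "fwhm")
  expect_warning(generate_noise(5, 31, 0.2, seed = 1), "clamped")
})

test_that("every node has unit variance, zero mean, normal marginals", {
  y <- generate_noise(10000, 101, 20, seed = 42)
  v <- apply(y, 2, var)
  expect_true(all(abs(v - 1) < 0.05))          # Monte Carlo bound at J = 10,000
  expect_true(all(abs(colMeans(y)) < 0.05))
  # marginals are exactly N(0,1) by construction; pooled KS distance should
  # be small even though within-row values are correlated
  d <- suppressWarnings(ks.test(as.numeric(y[1:500, ]), pnorm))$statistic
  expect_lt(unname(d), 0.03)
})

test_that("autocorrelation matches both the closed form and a convolution oracle", {
  fwhm <- 20
  y <- generate_noise(4000, 101, fwhm, seed = 7)
  # independent oracle: autocorrelation of white noise convolved with the
  # discrete Gaussian kernel, computed by direct numerical convolution
  sdk <- fwhm / sqrt(8 * log(2))
  k <- exp(-(-80:80)^2 / (2 * sdk^2))
  oracle_rho <- function(d) sum(k[1:(161 - d)] * k[(1 + d):161]) / sum(k^2)
  for (d in c(1, 5, 10)) {
    emp <- mean(vapply(1:(101 - d), function(x) cor(y[, x], y[, x + d]), 0))
    expect_lt(abs(emp - exp(-2 * log(2) * d^2 / fwhm^2)), 0.02)
    expect_lt(abs(emp - oracle_rho(d)), 0.02)
  }
})

test_that("fwhm at the clamp floor reduces to near-white noise", {
  y <- generate_noise(3000, 51, 0.5, seed = 11)
  lag1 <- mean(vapply(1:50, function(x) cor(y[, x], y[, x + 1]), 0))
  # theory for fwhm = 0.5: exp(-2 log 2 / 0.25) ~ 0.004
  expect_lt(abs(lag1), 0.05)
  expect_lt(abs(var(as.numeric(y)) - 1), 0.05)
})

test_that("gaussian pulse matches its definition, symmetry, and edge cases", {
  g <- gaussian_pulse(101, center = 50, sigma = 3, amp = 2.3)
  expect_equal(g[51], 2.3)                               # node 50, 0-based
  expect_equal(g[48], 2.3 * exp(-1 / 2))
  expect_equal(g[54], 2.3 * exp(-1 / 2))
  # interior center: symmetric about the center node
  expect_equal(g[51 - (1:20)], g[51 + (1:20)])

  # boundary signal: center at/beyond the last node -- only the rising tail
  gb <- gaussian_pulse(101, center = 101, sigma = 3, amp = 2.3)
  expect_true(all(diff(gb) > 0))
  expect_equal(gb[101], 2.3 * exp(-1 / 18))

  expect_identical(gaussian_pulse(101, 50, 3, 0), numeric(101))
  expect_identical(gaussian_pulse(101, 50, 0, 2.3), numeric(101))
  expect_error(gaussian_pulse(101, 50, -1, 1), "sigma")
})

test_that("synthesized designs carry the pulse where the analysis looks for it", {
  # paired: the sample difference carries the pulse with unit noise variance
  d <- synthesize_dataset(4000, 51, 10, center = 25, sigma = 5, amp = 1.5,
                          design = "paired", seed = 3)
  diffs <- unclass(d$sampleB) - unclass(d$sampleA)
  expect_lt(max(abs(colMeans(diffs) - d$signal)), 0.1)
  expect_lt(abs(mean(apply(diffs, 2, var)) - 1), 0.05)

  # one-sample: every observation offset by the pulse; amp = 0 is pure noise
  d1 <- synthesize_dataset(50, 51, 10, 25, 5, 2, design = "one-sample", seed = 4)
  d0 <- synthesize_dataset(50, 51, 10, 25, 5, 0, design = "one-sample", seed = 4)
  expect_equal(unclass(d1$sample) - unclass(d0$sample),
               matrix(d1$signal, 50, 51, byrow = TRUE))
  expect_identical(unclass(d0$sample), unclass(generate_noise(50, 51, 10, seed = 4)))

  # regression: observation j gets the pulse scaled by its centered covariate
  cov <- c(2, 4, 6, 8, 10)
  dr <- synthesize_dataset(5, 51, 10, 25, 5, 1.2, design = "regression",
                           covariate = cov, seed = 5)
  base <- generate_noise(5, 51, 10, seed = 5)
  expect_equal(unclass(dr$sample) - unclass(base),
               outer(cov - mean(cov), dr$signal))

  expect_error(synthesize_dataset(5, 51, 10, 25, 5, 1, "regression",
                                  covariate = 1:4), "covariate")
  expect_error(synthesize_dataset(5, 51, 10, 25, 5, 1, "regression",
                                  covariate = rep(2, 5)), "non-constant")
})
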