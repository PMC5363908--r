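# direct-formula oracles, independent of the implementation path
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

test_that("correlations match hand formulas and handle degeneracies", {
  x <- 1:6
  expect_equal(correlation(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlation(x, -x, "pearson")$estimate, -1)
  expect_equal(correlation(x, -x, "spearman")$estimate, -1)
  set.seed(30)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- correlation(a, b, "pearson")
    want <- pearson_oracle(a, b)
    expect_equal(got$estimate, want$r, tolerance = 1e-12)
    expect_equal(got$p.value, want$p, tolerance = 1e-10)
  }
  expect_error(correlation(1:2, 1:2), "3")
  expect_error(correlation(rep(1, 5), 1:5), "constant")
  expect_error(correlation(1:4, 1:5), "lengths")
  # invariance under positive affine rescaling (Pearson) and any monotone
  # transform (Spearman)
  set.seed(31)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(correlation(3 * a + 2, b, "pearson")$estimate,
               correlation(a, b, "pearson")$estimate, tolerance = 1e-12)
  expect_equal(correlation(exp(a), b, "spearman")$estimate,
               correlation(a, b, "spearman")$estimate, tolerance = 1e-12)
})

test_that("RMS error is the root mean square of OLS residuals", {
  x <- 1:6
  expect_equal(rms_error(x, 3 * x - 2), 0)
  # unit residuals constructed orthogonal to the regressors, so OLS
  # recovers the known line and the residual RMS is exactly 1
  xr <- c(1, 2, 3, 4)
  yr <- 2 * xr + 5 + c(1, -1, -1, 1)
  expect_equal(rms_error(xr, yr), 1)
  expect_error(rms_error(1:2, 1:2), "3")
  set.seed(32)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    fit <- lm(b ~ a)
    expect_equal(rms_error(a, b), sqrt(mean(resid(fit)^2)), tolerance = 1e-10)
    expect_equal(rms_error(a, b, divisor = "n-2"),
                 sqrt(sum(resid(fit)^2) / (n - 2)), tolerance = 1e-10)
  }
})

test_that("percent CV is 100 x sample SD over mean", {
  expect_equal(cv_percent(rep(4.2, 6)), 0)
  expect_equal(cv_percent(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(cv_percent(c(90, 110)), 14.1421356, tolerance = 1e-6)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
  expect_error(cv_percent(5), "2")
})

test_that("Bland-Altman reports bias, limits of agreement and proportional bias", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, -2)
  expect_equal(ba$loa_low, -3.96)
  expect_equal(ba$loa_high, -0.04)
  expect_equal(ba$n, 3L)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  off <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(off$bias, 1)
  expect_equal(off$loa_low, 1)
  expect_equal(off$diff_slope, 0)

  expect_error(bland_altman(1:2, 1:2), "3")

  # antisymmetry: swapping the methods mirrors bias and limits
  set.seed(33)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- bland_altman(x, y); g <- bland_altman(y, x)
    expect_equal(f$bias, -g$bias, tolerance = 1e-12)
    expect_equal(f$loa_low, -g$loa_high, tolerance = 1e-12)
    expect_equal(f$loa_high, -g$loa_low, tolerance = 1e-12)
    # oracle: direct formula
    d <- x - y
    expect_equal(f$bias, mean(d), tolerance = 1e-12)
    expect_equal(f$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-10)
    fit <- summary(lm(d ~ I((x + y) / 2)))
    expect_equal(f$diff_slope, unname(fit$coefficients[2, 1]),
                 tolerance = 1e-10)
    expect_equal(f$diff_r2, fit$r.squared, tolerance = 1e-10)
  }
})
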