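#' Correlation between two measurement series
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value (exact t distribution for Pearson; large-sample approximation
#' with tie correction for Spearman).
#'
#' @param x,y numeric series of equal length, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate` and `p.value`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' RMS error from linear-regression residuals
#'
#' Long-term precision error: ordinary least squares of `y` on `x`, then
#' the root mean square of the residuals (divisor `n` by default; the
#' residual-standard-error convention `n - 2` is available).
#'
#' @param x,y numeric series, n >= 3.
#' @param divisor `"n"` (pure RMS of residuals, default) or `"n-2"`.
#' @return the RMS error (units of `y`).
#' @export
rms_error <- function(x, y, divisor = c("n", "n-2")) {
  divisor <- match.arg(divisor)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  r <- resid(lm(y ~ x))
  den <- if (divisor == "n") n else n - 2L
  sqrt(sum(r^2) / den)
}

#' Coefficient of variation in percent
#'
#' Repeatability metric: 100 x sample standard deviation / mean.
#'
#' @param values numeric series, n >= 2, non-zero mean.
#' @return percent CV.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * sd(values) / m
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` against averages `(a + b) / 2`: bias (mean
#' difference), 95% limits of agreement (bias +/- 1.96 x sample SD of the
#' differences), and the regression of differences on averages used to
#' detect proportional bias.
#'
#' @param a,b paired numeric series, n >= 3.
#' @return An object of class `agreement_report`: `bias`, `loa_low`,
#'   `loa_high`, `diff_slope`, `diff_r2`, `diff_p`, `n`, plus the raw
#'   `differences` and `averages`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  avg <- (a + b) / 2
  bias <- mean(d)
  s <- sd(d)
  if (sd(avg) > 0 && s > 0) {
    fit <- suppressWarnings(summary(lm(d ~ avg)))
    slope <- fit$coefficients["avg", "Estimate"]
    r2 <- fit$r.squared
    p <- fit$coefficients["avg", "Pr(>|t|)"]
  } else {
    slope <- 0; r2 <- 0; p <- NA_real_
  }
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, diff_slope = slope,
                 diff_r2 = r2, diff_p = p, n = n,
                 differences = d, averages = avg),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  bias %.4g, limits of agreement [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  differences vs averages: slope %.4g, r^2 %.3g, p %s\n",
              x$diff_slope, x$diff_r2,
              ifelse(is.na(x$diff_p), "-", format.pval(x$diff_p))))
  invisible(x)
}

#' @export
#' @importFrom graphics abline plot
plot.agreement_report <- function(x, ...) {
  plot(x$averages, x$differences, xlab = "Average of methods",
       ylab = "Difference between methods", ...)
  abline(h = c(x$bias, x$loa_low, x$loa_high), lty = c(1, 2, 2))
  invisible(x)
}
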