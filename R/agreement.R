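# Agreement statistics: normality-gated paired tests, two-way mixed
# absolute-agreement ICC, Pearson correlation, Bland-Altman, delta summaries.

#' Normality-gated paired test
#'
#' Applies the Shapiro-Wilk test to the paired differences; if the
#' differences are compatible with normality (p >= 0.05) a paired t-test is
#' used, otherwise the Wilcoxon signed-rank test (exact p for small samples
#' without ties, per [stats::wilcox.test()] defaults).
#'
#' @param x,y paired numeric samples of equal length >= 3.
#' @return list with `test` (`"paired_t"` or `"wilcoxon"`), two-sided
#'   `p_value`, and `shapiro_p`.
#' @export
normality_gated_paired_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- y - x
  if (sd(d) < 1e-12)
    stop("paired differences are constant; the test is degenerate")
  sw <- shapiro.test(d)$p.value
  if (sw >= 0.05) {
    list(test = "paired_t", p_value = t.test(y, x, paired = TRUE)$p.value,
         shapiro_p = sw)
  } else {
    list(test = "wilcoxon",
         p_value = wilcox.test(y, x, paired = TRUE)$p.value,
         shapiro_p = sw)
  }
}

#' Two-way mixed absolute-agreement ICC, single measure
#'
#' ICC(A,1): `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the
#' two-way ANOVA mean squares of an n subjects x k raters matrix, with a
#' 95% confidence interval from the F-distribution bounds
#' (Satterthwaite degrees of freedom). Reliability is labelled excellent at
#' 0.9 and above and good at 0.75 and above.
#'
#' @param data numeric matrix, rows = subjects, columns = raters/trials;
#'   no missing cells.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `n_subjects`, `n_raters`, `label`.
#' @export
icc_absolute_agreement <- function(data, conf = 0.95) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells are not supported (no imputation)")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(data)
  row_m <- rowMeans(data); col_m <- colMeans(data)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((data - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf
  if (mse < 1e-30 && msc < 1e-30) {
    # identical raters: perfect agreement, degenerate F bounds
    lo <- hi <- icc
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    lo <- min(lo, icc); hi <- max(hi, icc)
  }
  label <- if (icc >= 0.9) "excellent" else if (icc >= 0.75) "good"
  else "moderate/poor"
  structure(list(icc = icc, ci_lower = lo, ci_upper = hi,
                 n_subjects = n, n_raters = k, label = label),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, 95%% CI [%.3f, %.3f] (%d subjects x %d raters, %s reliability)\n",
              x$icc, x$ci_lower, x$ci_upper, x$n_subjects, x$n_raters,
              x$label))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `mean(y - x)`; the repeatability coefficient
#' (RPC) is 1.96 times the SD of the differences; the limits of agreement
#' are `bias +/- RPC`; the coefficient of variation (CV) is the SD of the
#' differences divided by the mean of the pairwise averages, in percent.
#'
#' @param x,y paired numeric measurements.
#' @return object of class `bland_altman`: `bias`, `rpc`, `cv` (percent;
#'   `NA` when the pooled mean is zero), `loa_lower`, `loa_upper`, and the
#'   per-pair `mean`/`diff` vectors for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  s <- sd(d)
  rpc <- 1.96 * s
  pooled <- mean(m)
  cv <- if (abs(pooled) < 1e-12) {
    warning("pooled mean is zero; CV undefined")
    NA_real_
  } else 100 * s / pooled
  structure(list(bias = bias, rpc = rpc, cv = cv,
                 loa_lower = bias - rpc, loa_upper = bias + rpc,
                 mean = m, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, RPC %.4g, LoA [%.4g, %.4g], CV %.3g%%\n",
              x$bias, x$rpc, x$loa_lower, x$loa_upper, x$cv))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$mean, x$diff, xlab = "mean of pair",
                 ylab = "difference (y - x)", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return list with `r` and `p_value` (two-sided, t transform).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (sd(x) < 1e-15 || sd(y) < 1e-15) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Difference summaries between algorithm and manual measurements
#'
#' Delta = algorithm - manual; reports the mean and SD of the signed and
#' absolute differences.
#'
#' @param auto_vals,manual_vals paired numeric measurements.
#' @return list with `mean_delta`, `sd_delta`, `mean_abs_delta`,
#'   `sd_abs_delta`.
#' @export
delta_summary <- function(auto_vals, manual_vals) {
  if (length(auto_vals) != length(manual_vals)) stop("inputs must be paired")
  d <- auto_vals - manual_vals
  list(mean_delta = mean(d), sd_delta = if (length(d) > 1L) sd(d) else 0,
       mean_abs_delta = mean(abs(d)),
       sd_abs_delta = if (length(d) > 1L) sd(abs(d)) else 0)
}
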