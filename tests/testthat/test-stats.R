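test_that("the Shapiro-Wilk gate routes to the right paired test", {
  set.seed(31)
  x <- rnorm(50)
  expect_error(normality_gated_paired_test(x, x), "constant|degenerate")
  y <- x + rnorm(50, 0, 0.5)
  res <- normality_gated_paired_test(x, y)
  expect_equal(res$test, "paired_t")
  expect_equal(res$p_value,
               t.test(y, x, paired = TRUE)$p.value)
  # heavy-tailed differences route to Wilcoxon in nearly all replicates
  n_wilcox <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(50)
    b <- a + rcauchy(50)
    if (normality_gated_paired_test(a, b)$test == "wilcoxon")
      n_wilcox <- n_wilcox + 1L
  }
  expect_gte(n_wilcox, 95)
})

test_that("the Wilcoxon branch matches the exact permutation distribution", {
  # brute-force oracle: enumerate all 2^n sign assignments of |d|
  exact_wilcox_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    mean(pmin(2 * pmin(
      vapply(v_obs, function(v) mean(v_all <= v), 1),
      vapply(v_obs, function(v) mean(v_all >= v), 1)), 1))
  }
  set.seed(8)
  for (i in 1:5) {
    d <- round(rnorm(9, 0.3, 1), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    p_pkg <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(p_pkg, exact_wilcox_p(d), tolerance = 1e-10)
  }
})

test_that("ICC(A,1) matches the frozen reference implementation values", {
  # two-way mixed absolute-agreement ICC on a fixed 6 x 4 matrix; expected
  # values frozen from an independent implementation (pingouin 0.6.1)
  X <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  res <- icc_absolute_agreement(X)
  expect_equal(res$icc, 0.289764, tolerance = 1e-5)
  expect_lt(abs(res$ci_lower - 0.02), 0.005)
  expect_lt(abs(res$ci_upper - 0.76), 0.005)
  expect_equal(res$n_subjects, 6)
  expect_equal(res$n_raters, 4)
})

test_that("ICC handles degenerate and simulated-recovery cases", {
  set.seed(12)
  subj <- rnorm(20, 10, 2)
  X <- cbind(subj, subj)
  res <- icc_absolute_agreement(X)
  expect_equal(res$icc, 1)
  expect_equal(res$label, "excellent")
  # parameter recovery: icc = sigma_s^2 / (sigma_s^2 + sigma_e^2) = 0.5
  set.seed(13)
  s <- rnorm(500, 0, 1)
  Y <- cbind(s + rnorm(500), s + rnorm(500))
  expect_lt(abs(icc_absolute_agreement(Y)$icc - 0.5), 0.05)
  # no subject variance: icc ~ 0
  Z <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(icc_absolute_agreement(Z)$icc), 0.05)
  expect_error(icc_absolute_agreement(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("ICC is invariant under common shifts and positive rescaling", {
  set.seed(14)
  s <- rnorm(80)
  X <- cbind(s + rnorm(80, 0, 0.7), s + rnorm(80, 0, 0.7))
  base <- icc_absolute_agreement(X)$icc
  expect_equal(icc_absolute_agreement(X + 100)$icc, base, tolerance = 1e-9)
  expect_equal(icc_absolute_agreement(X * 3.7)$icc, base, tolerance = 1e-9)
})

test_that("Bland-Altman components satisfy their definitions", {
  set.seed(15)
  x <- rnorm(40, 100, 10)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$rpc, 0)
  expect_equal(bland_altman(x, x)$cv, 0)
  ba <- bland_altman(x, x + 5)
  expect_equal(ba$bias, 5)
  expect_equal(ba$rpc, 0)
  y <- x + rnorm(40)
  ba2 <- bland_altman(x, y)
  expect_equal(ba2$rpc / sd(y - x), 1.96)
  expect_equal(ba2$loa_upper - ba2$loa_lower, 2 * ba2$rpc)
  expect_equal(ba2$cv, 100 * sd(y - x) / mean((x + y) / 2))
  # antisymmetry of the bias, symmetry of the RPC
  ba3 <- bland_altman(y, x)
  expect_equal(ba3$bias, -ba2$bias)
  expect_equal(ba3$rpc, ba2$rpc)
  expect_warning(bland_altman(c(-1, 1), c(1, -1)), "zero")
})

test_that("Pearson correlation and delta summaries match closed forms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 5)), "variance")
  set.seed(16)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(pearson(a, b)$r), 0.05)
  ds <- delta_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ds), c(mean_delta = 0, sd_delta = 0,
                             mean_abs_delta = 0, sd_abs_delta = 0))
  ds2 <- delta_summary(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ds2$mean_delta, 1)
  expect_equal(ds2$sd_delta, 0)
  ds3 <- delta_summary(c(2, 0, 2, 0), c(1, 1, 1, 1))
  expect_equal(ds3$mean_delta, 0)
  expect_equal(ds3$mean_abs_delta, 1)
})
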