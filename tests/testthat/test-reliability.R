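long_df <- function(m) {
  data.frame(subject = rep(seq_len(nrow(m)), ncol(m)),
             session = rep(seq_len(ncol(m)), each = nrow(m)),
             value = as.vector(m))
}

test_that("perfect agreement gives ICC = 1 and identity shuffles break it", {
  v <- c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4, 2.9, 3.3, 1.8, 2.5)
  res <- icc_two_way(long_df(cbind(v, v)))
  expect_equal(res$icc, 1)
  expect_equal(res$icc_ci_low, 1)
  # values shuffled independently across subjects destroy subject variance
  set.seed(41)
  n <- 200
  x <- rnorm(n)
  m <- cbind(sample(x), sample(x))
  res0 <- icc_two_way(long_df(m))
  expect_lt(abs(res0$icc), 0.15)
})

test_that("ICC(A,1) matches a from-scratch ANOVA mean-squares computation", {
  m <- matrix(c(9.1, 8.2, 7.6, 10.4, 6.9, 8.8,
                9.4, 8.0, 7.9, 10.9, 7.3, 8.5), ncol = 2)
  res <- icc_two_way(long_df(m))
  # independent oracle: mean squares from aov()
  df <- long_df(m)
  df$subject <- factor(df$subject); df$session <- factor(df$session)
  tab <- summary(stats::aov(value ~ subject + session, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["session", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 6; k <- 2
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(res$icc, icc_hand, tolerance = 1e-10)
  expect_equal(res$msr, msr, tolerance = 1e-10)
  expect_equal(res$mse, mse, tolerance = 1e-10)
  expect_true(res$icc_ci_low <= res$icc && res$icc <= res$icc_ci_high)
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(42)
  m <- matrix(rnorm(40, 10, 2), ncol = 2)
  base <- icc_two_way(long_df(m))$icc
  expect_equal(icc_two_way(long_df(m + 7.3))$icc, base, tolerance = 1e-12)
  expect_equal(icc_two_way(long_df(m * 3.1))$icc, base, tolerance = 1e-12)
})

test_that("degenerate and unbalanced inputs raise named errors", {
  flat <- long_df(matrix(5, 4, 2))
  expect_error(icc_two_way(flat), class = "octa_degenerate")
  df <- long_df(matrix(rnorm(8), 4, 2))[-1, ]
  expect_error(icc_two_way(df), class = "octa_unbalanced")
})

test_that("ICC recovers the variance-ratio ground truth in simulation", {
  set.seed(43)
  n <- 500; sb <- 2; sw <- 1
  subj <- rnorm(n, 0, sb)
  m <- cbind(subj + rnorm(n, 0, sw), subj + rnorm(n, 0, sw))
  res <- icc_two_way(long_df(m))
  expect_equal(res$icc, sb^2 / (sb^2 + sw^2), tolerance = 0.03 / 0.8)
  expect_lt(abs(res$icc - sb^2 / (sb^2 + sw^2)), 0.03)
})

test_that("coefficient of repeatability is 1.96 times the SD of differences", {
  m <- matrix(c(1.0, 2.0, 3.0, 4.0, 5.0,
                1.1, 1.8, 3.3, 3.9, 5.4), ncol = 2)
  res <- coefficient_of_repeatability(long_df(m))
  d <- m[, 1] - m[, 2]
  expect_equal(res$cr, 1.96 * sd(d), tolerance = 1e-12)
  expect_true(res$cr_ci_low <= res$cr && res$cr <= res$cr_ci_high)
  # identical sessions
  same <- long_df(cbind(1:5, 1:5))
  expect_equal(coefficient_of_repeatability(same)$cr, 0)
})

test_that("CR converges to 1.96 sigma for Gaussian differences", {
  set.seed(44)
  n <- 10000; sigma <- 0.7
  base <- rnorm(n, 10, 3)
  m <- cbind(base, base + rnorm(n, 0, sigma))
  res <- coefficient_of_repeatability(long_df(m))
  expect_equal(res$cr / sigma, 1.96, tolerance = 0.05 / 1.96)
})

test_that("CR and limits of agreement scale linearly with the data", {
  set.seed(45)
  m <- matrix(rnorm(30, 5, 1), ncol = 2)
  c1 <- coefficient_of_repeatability(long_df(m))$cr
  c3 <- coefficient_of_repeatability(long_df(m * 3))$cr
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
  ba1 <- bland_altman(m[, 1], m[, 2])
  ba3 <- bland_altman(3 * m[, 1], 3 * m[, 2])
  expect_equal(ba3$loa_high, 3 * ba1$loa_high, tolerance = 1e-12)
  expect_equal(ba3$mean_difference, 3 * ba1$mean_difference, tolerance = 1e-12)
})

test_that("Bland-Altman reproduces hand-computed mean and limits", {
  a <- c(1, 2, 3); b <- c(1.1, 2.1, 3.1)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_difference, -0.1)
  expect_equal(ba$loa_low, -0.1)
  expect_equal(ba$loa_high, -0.1)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  set.seed(46)
  x <- rnorm(8); y <- rnorm(8)
  ba8 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba8$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(ba8$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1:2, 1:2), class = "octa_too_few")
})

test_that("the ICC precision rule inverts to the published design point", {
  # 30 subjects, 2 raters, CI width 0.2 -> detectable ICC about 0.86
  icc <- icc_for_width(30, 2, 0.2)
  expect_equal(icc, 0.86, tolerance = 0.02 / 0.86)
  expect_lt(abs(icc - 0.86), 0.02)
  # round trip
  expect_equal(icc_ci_width(30, 2, icc), 0.2, tolerance = 1e-9)
})

test_that("CI width shrinks with higher ICC and larger n", {
  w <- icc_ci_width(30, 2, c(0.5, 0.7, 0.9, 0.99, 0.999))
  expect_true(all(diff(w) < 0))
  expect_lt(icc_ci_width(30, 2, 0.999), 0.01)
  expect_lt(icc_ci_width(120, 2, 0.86), icc_ci_width(30, 2, 0.86))
})
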