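test_that("mask CSA follows the calibration and component rules", {
  m <- matrix(0L, 32, 32); m[5:14, 5:14] <- 1L  # 100 px
  expect_equal(csa_mm2(m, 0.1), 1.00)
  # two components: only the largest is counted when the flag is on
  m2 <- m; m2[25:28, 25:29] <- 1L  # extra 20 px island
  expect_equal(csa_mm2(m2, 0.1, largest_component_only = TRUE), 1.00)
  expect_equal(csa_mm2(m2, 0.1, largest_component_only = FALSE), 1.20)
  # halving the spacing quarters the CSA
  set.seed(5)
  for (k in 1:10) {
    r <- matrix(rbinom(256, 1, 0.3), 16, 16)
    expect_equal(csa_mm2(r, 0.05, FALSE), csa_mm2(r, 0.1, FALSE) / 4)
  }
  expect_error(csa_mm2(matrix(0.5, 2, 2), 0.1), "binary")
  expect_error(csa_mm2(m, 0), "positive")
})

test_that("largest_component uses 4-connectivity", {
  # two diagonal pixels are NOT 4-connected
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L; m[2, 3] <- 1L
  out <- largest_component(m)
  expect_equal(sum(out), 2)       # the 2-pixel 4-connected pair wins
  expect_equal(out[1, 1], 0L)
})

test_that("paired-difference inference matches t.test and printed summaries", {
  set.seed(19)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    a <- rnorm(n, 5, 1); b <- a + rnorm(n, 0.2, 0.5)
    pd <- paired_difference_inference(a, b)
    tt <- stats::t.test(a, b, paired = TRUE)
    expect_equal(pd$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(pd$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(c(pd$ci_low, pd$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-12)
  }
  d <- paired_difference_inference(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d$mean_diff, 0)
  expect_true(is.na(d$t_stat))
  expect_error(paired_difference_inference(1:3, 1:4), "mismatch")
  expect_error(paired_difference_inference(1, 1), "2 pairs")
})

test_that("Fisher-z correlation intervals match cor.test", {
  set.seed(20)
  for (k in 1:15) {
    n <- sample(10:80, 1)
    x <- rnorm(n); y <- 0.7 * x + rnorm(n, 0, 0.6)
    pr <- pearson_with_fisher_ci(x, y)
    ct <- stats::cor.test(x, y)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(c(pr$ci_low, pr$ci_high), as.numeric(ct$conf.int),
                 tolerance = 1e-3)
  }
  x <- rnorm(20)
  pr <- pearson_with_fisher_ci(x, x)
  expect_equal(pr$r, 1)
  expect_gt(pr$ci_low, 0.999)
  expect_error(pearson_with_fisher_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_with_fisher_ci(rnorm(3), rnorm(3)), "n >= 4")
})

test_that("ICC(2,1) reproduces a from-scratch ANOVA on a toy matrix", {
  # 6 subjects x 2 methods, integer ratings
  r <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  ic <- icc_2_1(r)
  # independent ANOVA by raw summation formulas
  n <- 6; k <- 2
  grand <- mean(r)
  ssr <- k * sum((rowMeans(r) - grand)^2)
  ssc <- n * sum((colMeans(r) - grand)^2)
  sse <- sum((r - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(ic$icc, icc_ref, tolerance = 1e-12)
  # identical columns: perfect agreement
  same <- cbind(1:6, 1:6)
  expect_equal(icc_2_1(same)$icc, 1)
  expect_error(icc_2_1(cbind(c(1, NA, 3, 4, 5), 1:5)), "missing")
})

test_that("ICC(2,1) recovers the variance-ratio ground truth in simulation", {
  # subjects ~ N(0, s2_s), methods add N(0, s2_e): ICC = s2_s/(s2_s+s2_e)
  s2_s <- 1.0; s2_e <- 0.4
  truth <- s2_s / (s2_s + s2_e)
  set.seed(28)
  est <- replicate(500, {
    subj <- rnorm(30, 0, sqrt(s2_s))
    m <- cbind(subj + rnorm(30, 0, sqrt(s2_e)),
               subj + rnorm(30, 0, sqrt(s2_e)))
    icc_2_1(m)$icc
  })
  se <- stats::sd(est) / sqrt(500)
  expect_lt(abs(mean(est) - truth), 3 * se + 0.02)  # small-sample bias margin
  # interval behaves like an interval
  set.seed(29)
  subj <- rnorm(40, 5, 1)
  m <- cbind(subj + rnorm(40, 0, 0.3), subj + rnorm(40, 0, 0.3))
  ic <- icc_2_1(m)
  expect_lt(ic$ci_low, ic$icc)
  expect_gt(ic$ci_high, ic$icc)
  expect_true(ic$icc >= -1 && ic$icc <= 1)
})

test_that("ICC rises monotonically as method noise shrinks", {
  iccs <- sapply(c(0.8, 0.3, 0.05), function(s_e) {
    set.seed(33)
    subj <- rnorm(50, 10, 2)
    icc_2_1(cbind(subj + rnorm(50, 0, s_e), subj + rnorm(50, 0, s_e)))$icc
  })
  expect_true(all(diff(iccs) > 0))
})

test_that("Bland-Altman bias and limits follow the standard definition", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(0, 2), c(1, 1))  # differences -1, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  # ~95% of normal differences fall inside the limits
  set.seed(26)
  x <- rnorm(1e4, 3, 1); y <- x + rnorm(1e4, 0.1, 0.4)
  ba2 <- bland_altman(x, y)
  inside <- mean(ba2$data$diff > ba2$loa_low & ba2$data$diff < ba2$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("the full agreement report is internally consistent", {
  set.seed(30)
  manual <- rnorm(60, 8, 2)
  pred <- manual - rnorm(60, 0.3, 0.5)  # automated under-measures slightly
  ar <- agreement_report(manual, pred)
  expect_lte(ar$ci_low, ar$mean_diff)
  expect_gte(ar$ci_high, ar$mean_diff)
  expect_lte(ar$ba_loa_low, ar$ba_bias)
  expect_gte(ar$ba_loa_high, ar$ba_bias)
  expect_true(abs(ar$pearson_r) <= 1 && abs(ar$icc21) <= 1)
  expect_equal(ar$ba_bias, ar$mean_diff)  # both are mean(manual - predicted)
  expect_gt(ar$mean_diff, 0)              # injected positive bias is detected
})
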