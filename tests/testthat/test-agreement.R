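test_that("rmse follows the closed form and its invariances", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:4, 1:4 + 5), 5)
  expect_equal(rmse(c(1, 2, 3), c(2, 4, 6)), sqrt(14 / 3))
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_equal(rmse(x + 3.7, y + 3.7), rmse(x, y), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("pcc matches the product-moment formula and affine invariance", {
  x <- 1:10
  expect_equal(pcc(x, 2 * x + 1)$estimate, 1)
  expect_equal(pcc(x, -x)$estimate, -1)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pcc(a, b)$estimate, brute, tolerance = 1e-12)
  expect_equal(pcc(3 + 2 * a, b)$estimate, pcc(a, b)$estimate,
               tolerance = 1e-12)
  expect_error(pcc(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("cv_percent uses the sample standard deviation over the mean", {
  expect_identical(cv_percent(c(10, 10)), 0)
  expect_equal(cv_percent(c(8, 12)), 28.28427, tolerance = 1e-4)
  set.seed(6)
  v <- runif(5, 10, 20)
  expect_equal(cv_percent(v), sd(v) / mean(v) * 100, tolerance = 1e-12)
  expect_error(cv_percent(c(-1, 1)), "mean is zero")
  expect_error(cv_percent(5), "at least 2")
})

test_that("granger detects a planted lead-lag structure", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  y <- 0.9 * c(rep(0, 3), x[1:(n - 3)]) + rnorm(n, sd = 0.1)
  g <- granger_agreement(x, y, max_lag = 10, difference = FALSE)
  expect_true(g$agree)
  expect_lt(g$p_fwd, 0.01)
})

test_that("granger flags temporal agreement of a shifted FJA trace", {
  rec <- zero_noise_limb("trot")
  x <- filtered_imu(rec)$values
  y <- c(x[-(1:10)], x[1:10])
  g <- granger_agreement(x, y, max_lag = 20)
  expect_true(g$agree)
})

test_that("granger matches the reference implementation at a fixed order", {
  skip_if_not_installed("lmtest")
  set.seed(13)
  x <- as.numeric(arima.sim(list(ar = 0.5), 400))
  y <- 0.4 * c(0, 0, x[1:398]) + as.numeric(arima.sim(list(ar = 0.3), 400))
  mine <- fjagait:::granger_one_direction(cause = x, target = y,
                                          max_lag = 3, ic = "bic")
  # evaluate the reference at the same lag order on the same sample
  ref <- lmtest::grangertest(y ~ x, order = mine$lag)
  # common-sample embedding differs by (max_lag - lag) leading rows when
  # lag < max_lag; re-run ours at max_lag = lag for an exact match
  mine2 <- fjagait:::granger_one_direction(cause = x, target = y,
                                           max_lag = mine$lag, ic = "bic")
  expect_equal(mine2$statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(mine2$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("granger rejects unusable inputs", {
  expect_error(granger_agreement(rep(1, 100), rnorm(100)), "constant")
  expect_error(granger_agreement(rnorm(50), rnorm(50), max_lag = 20),
               "too short")
})

test_that("granger type-I error stays near its nominal level", {
  set.seed(21)
  n_rep <- 500
  rej_fwd <- rej_rev <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(150); y <- rnorm(150)
    g <- granger_agreement(x, y, max_lag = 4, difference = FALSE)
    rej_fwd[i] <- g$p_fwd < 0.01
    rej_rev[i] <- g$p_rev < 0.01
  }
  env <- qbinom(c(0.005, 0.995), n_rep, 0.01)
  expect_gte(sum(rej_fwd), env[1]); expect_lte(sum(rej_fwd), env[2])
  expect_gte(sum(rej_rev), env[1]); expect_lte(sum(rej_rev), env[2])
})

test_that("bland-altman handles exact agreement and constant offsets", {
  x <- rnorm(20, 10)
  b0 <- bland_altman_rm(x, x, method = "pooled")
  expect_identical(b0$bias, 0)
  expect_identical(b0$loa_low, 0)
  expect_identical(b0$loa_high, 0)
  b5 <- bland_altman_rm(x + 5, x, method = "pooled")
  expect_equal(b5$bias, 5)
  expect_equal(c(b5$loa_low, b5$loa_high), c(5, 5))
})

test_that("bland-altman limits recover the generating noise scale", {
  set.seed(11)
  subj <- rep(1:10, each = 500)
  x <- rnorm(5000, mean = 50, sd = 8)
  y <- x + rnorm(5000, sd = 2)
  for (m in c("pooled", "rm_corrected")) {
    ba <- bland_altman_rm(x, y, subject = subj, method = m)
    expect_lt(abs(ba$bias), 0.15)
    expect_lt(abs(ba$loa_low - (-3.92)), 0.2)
    expect_lt(abs(ba$loa_high - 3.92), 0.2)
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  }
})

test_that("rm-corrected limits widen under subject-specific bias", {
  set.seed(12)
  subj <- rep(1:8, each = 50)
  bias_s <- rnorm(8, sd = 3)[subj]
  x <- rnorm(400, 40, 5)
  y <- x + bias_s + rnorm(400, sd = 1)
  pooled <- bland_altman_rm(x, y, subject = subj, method = "pooled")
  rmc <- bland_altman_rm(x, y, subject = subj, method = "rm_corrected")
  expect_gte(rmc$loa_high - rmc$loa_low,
             0.95 * (pooled$loa_high - pooled$loa_low))
  # both approximate sd = sqrt(3^2 + 1^2); rm-corrected from components
  expect_lt(abs(rmc$sd_total - sqrt(10)), 1)
})

test_that("bland-altman falls back to pooled when subjects are unusable", {
  x <- rnorm(5); y <- x + 1
  expect_warning(out <- bland_altman_rm(x, y, subject = c(1, 1, 2, 3, 4)),
                 "falling back")
  expect_identical(out$method, "pooled")
  expect_warning(bland_altman_rm(x, y), "no subject")
})

test_that("agreement report bundles the per-trial measures", {
  rec <- noisy_limb("walk", seed = 8)
  out <- analyze_limb_pair(rec)
  ag <- out$agreement
  expect_s3_class(ag, "fja_agreement")
  expect_lt(ag$rmse_deg, 10)
  expect_gt(ag$pcc, 0.9)
  expect_true(ag$granger$agree)
  expect_true(ag$bland_altman$loa_low <= ag$bland_altman$bias)
})
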