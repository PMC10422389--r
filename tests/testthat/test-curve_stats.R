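test_that("zero-phase Butterworth filter has the designed gains", {
  # DC: constants pass through unchanged
  y <- butterworth_lowpass(rep(2.5, 100), fs = 100, fc = 10)
  expect_lt(max(abs(y - 2.5)), 1e-9)

  amp <- function(x, keep) sqrt(2 * mean(x[keep]^2))
  t <- (0:499) / 100
  keep <- 101:400
  # gain 0.5 at the cutoff (-3 dB twice)
  y_fc <- butterworth_lowpass(sin(2 * pi * 10 * t), 100, 10)
  expect_equal(amp(y_fc, keep) / amp(sin(2 * pi * 10 * t), keep), 0.5,
               tolerance = 0.02)
  # deep stopband at 4x the cutoff: |H|^2 = 1/(1+(f/fc)^8) squared again
  y_40 <- butterworth_lowpass(sin(2 * pi * 40 * t), 100, 10)
  expect_lt(amp(y_40, keep) / amp(sin(2 * pi * 40 * t), keep), 1e-4)
  # no phase shift: a passband sine comes through essentially unchanged
  # (any group delay would show up as a large pointwise difference)
  x <- sin(2 * pi * 2 * t)
  y2 <- butterworth_lowpass(x, 100, 10)
  expect_lt(max(abs(y2[keep] - x[keep])), 1e-3)
})

test_that("filter validates its inputs", {
  expect_error(butterworth_lowpass(rnorm(10), 100, 10),
               class = "footkinetics_validation_error")  # shorter than padding
  expect_warning(butterworth_lowpass(rnorm(100), 100, 50), "Nyquist")
  expect_error(butterworth_lowpass(rnorm(100), 100, -1),
               class = "footkinetics_validation_error")
})

test_that("stance resampling is linear with exact endpoints", {
  x <- seq(0, 10, length.out = 51)
  y <- resample_stance(x, 11, 41, n = 101)
  expect_equal(y[1], x[11]); expect_equal(y[101], x[41])
  expect_equal(diff(y), rep(diff(y)[1], 100), tolerance = 1e-12)

  expect_equal(resample_stance(rep(3.3, 50), 5, 45), rep(3.3, 101))

  # sampled sine matches the analytic curve to the interpolation-error bound
  fs <- 100
  tt <- (0:99) / fs
  x2 <- sin(2 * pi * 3 * tt)
  y2 <- resample_stance(x2, 1, 100, 101)
  t_out <- seq(tt[1], tt[100], length.out = 101)
  bound <- (2 * pi * 3)^2 / 8 * (1 / fs)^2          # max |f''| h^2 / 8
  expect_lt(max(abs(y2 - sin(2 * pi * 3 * t_out))), bound * 1.01)

  expect_error(resample_stance(x, 5, 45, n = 1),
               class = "footkinetics_validation_error")
})

test_that("peak extraction uses first occurrence and shifts with constants", {
  pct <- 0:100
  bell <- exp(-((pct - 75) / 12)^2) * 1.2
  p <- extract_params(bell)
  expect_equal(p$max_val, 1.2); expect_equal(p$t_max, 75)

  mono <- seq(0, 1, length.out = 101)
  expect_equal(extract_params(mono)$t_max, 100)
  expect_equal(extract_params(mono)$t_min, 0)

  plateau <- rep(0, 101); plateau[41:51] <- 2
  expect_equal(extract_params(plateau)$t_max, 40)   # first occurrence

  shifted <- extract_params(bell + 5)
  expect_equal(shifted$max_val, p$max_val + 5)
  expect_equal(shifted$min_val, extract_params(bell)$min_val + 5)
  expect_equal(shifted$t_max, p$t_max)
  expect_equal(shifted$t_min, extract_params(bell)$t_min)
})

test_that("mean/CI curves match the closed-form t interval", {
  curves <- matrix(rep(c(1, 2, 3), each = 10), 3, 10, byrow = TRUE)
  ci <- mean_ci_curves(rbind(curves[1, ], curves[1, ]))
  expect_equal(ci$lower, ci$upper)                   # identical curves: width 0

  ci2 <- mean_ci_curves(rbind(rep(2, 5), rep(-2, 5)))
  expect_equal(ci2$mean, rep(0, 5))
  expect_equal(ci2$upper, -ci2$lower)

  set.seed(41)
  x <- matrix(rnorm(10 * 101), 10, 101)
  ci3 <- mean_ci_curves(x)
  j <- 17
  m <- mean(x[, j]); s <- sd(x[, j])
  expect_equal(ci3$mean[j], m)
  expect_equal(ci3$upper[j], m + qt(0.975, 9) * s / sqrt(10), tolerance = 1e-12)

  # width shrinks as 1/sqrt(n) on homoscedastic curves
  set.seed(42)
  w <- function(n) {
    y <- matrix(rnorm(n * 50), n, 50)
    mean(mean_ci_curves(y)$upper - mean_ci_curves(y)$lower) /
      (2 * qt(0.975, n - 1))
  }
  expect_lt(w(160), w(10))
  expect_error(mean_ci_curves(matrix(1, 1, 5)),
               class = "footkinetics_validation_error")
})

test_that("ICC matches brute-force sums of squares and aov", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(6:12, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n, 0, 3)
    res <- icc(x)
    # independent oracle: explicit two-way ANOVA sums of squares
    gm <- mean(x)
    ssr <- k * sum((rowMeans(x) - gm)^2)
    ssc <- n * sum((colMeans(x) - gm)^2)
    sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                  outer(rep(1, n), colMeans(x)) + gm)^2)
    msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    expect_equal(res$consistency, (msr - mse) / msr, tolerance = 1e-10)
    expect_equal(res$agreement, (msr - mse) / (msr + (msc - mse) / n),
                 tolerance = 1e-10)
    # aov cross-check of the mean squares
    d <- data.frame(y = as.vector(x),
                    subj = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
    a <- summary(aov(y ~ subj + rater, d))[[1]]
    expect_equal(unname(res$ms["rows"]), a["subj", "Mean Sq"], tolerance = 1e-10)
    expect_equal(unname(res$ms["error"]), a["Residuals", "Mean Sq"],
                 tolerance = 1e-10)
  }
})

test_that("ICC behaves as the definitions require", {
  # perfect within-subject agreement with between-subject spread
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- icc(x)
  expect_equal(res$consistency, 1)
  expect_equal(res$agreement, 1)

  # constant offset between devices: consistency stays 1, agreement drops
  y <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4) + 2)
  res2 <- icc(y)
  expect_equal(res2$consistency, 1)
  expect_lt(res2$agreement, 1)

  # affine invariance of consistency; shift invariance of both
  set.seed(44)
  z <- matrix(rnorm(24), 8, 3) + rnorm(8)
  r0 <- icc(z); r_shift <- icc(z + 7); r_aff <- icc(3 * z - 2)
  expect_equal(r_shift$consistency, r0$consistency, tolerance = 1e-12)
  expect_equal(r_shift$agreement, r0$agreement, tolerance = 1e-12)
  expect_equal(r_aff$consistency, r0$consistency, tolerance = 1e-12)
  expect_lte(r0$agreement, r0$consistency + 1e-12)

  expect_warning(icc(matrix(5, 4, 2)), "variance")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "footkinetics_validation_error")
})
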