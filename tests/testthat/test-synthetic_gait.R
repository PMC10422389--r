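test_that("simulation is bitwise deterministic for a fixed seed", {
  m <- fast_model(seed = 51)
  a <- simulate_trial(m)
  b <- simulate_trial(m)
  expect_identical(a$trial$platform$frames, b$trial$platform$frames)
  expect_identical(a$trial$insole$frames, b$trial$insole$frames)
  expect_identical(a$trial$markers$positions, b$trial$markers$positions)
  c <- simulate_trial(fast_model(seed = 52))
  expect_false(identical(a$trial$platform$frames, c$trial$platform$frames))
})

test_that("the sampled platform peak force matches the configured profile", {
  m <- fast_model(seed = 53, noise_sd = 0)
  target <- m$force_profile$peaks[1] * m$body_mass * 9.81
  # grid quadrature of the raw field at the first peak instant
  geom <- simulate_trial(m)$trial$platform$geometry
  centers_foot <- sweep(cell_centers(geom), 2, m$foot_position, "-") %*%
    footkinetics:::rot2cw(m$progression_angle)
  f_raw <- sum(footkinetics:::field_kpa(centers_foot, 25, m)) * 1000 *
    geom$pitch_x * geom$pitch_y
  expect_lt(abs(f_raw - target) / target, 0.02)
  # the recorded peak additionally loses the sub-floor (< 4 kPa) tails
  tot <- total_force(simulate_trial(m)$trial$platform)
  expect_lt(abs(max(tot) - target) / target, 0.035)
})

test_that("blobs confined behind the MT axis give zero distal ground truth", {
  m <- fast_model(seed = 54, noise_sd = 0)
  m$blobs$cy <- c(0.03, 0.05, 0.06)   # all posterior to the MT axis (0.1125 m)
  m$blobs$sy <- c(0.010, 0.010, 0.008)
  gt <- ground_truth_kinetics(m)
  expect_lt(max(gt$forces$mt), 1e-3)
  expect_lt(max(gt$forces$mp), 1e-3)
  expect_gt(max(gt$forces$ankle), 500)
})

test_that("closed-form ground truth agrees with 1 mm quadrature", {
  m <- fast_model(seed = 55, noise_sd = 0)
  gt <- ground_truth_kinetics(m)
  L <- m$foot_length
  s_grid <- seq(0, 100, length.out = length(footkinetics:::stance_percents(m)))
  for (s in c(30, 55, 80)) {
    for (j in c("ankle", "mt", "mp")) {
      bnd <- switch(j, ankle = -Inf, mt = m$joint_fractions[["mt"]] * L,
                    mp = m$joint_fractions[["mp"]] * L)
      q <- field_quadrature(m, s, boundary = bnd, pitch = 0.001)
      # ground-truth force at this instant, from the closed form
      k <- which.min(abs(s_grid - s))
      f_cf <- gt$forces[[j]][round(s) + 1]
      expect_lt(abs(q$f - f_cf) / max(f_cf, 1), 0.001)
    }
  }
  # ankle flexion moment against the brute-force per-cell sum (global frame,
  # undone body-weight normalization and proximal rotation)
  s <- 75
  jc_foot <- c(0, m$joint_fractions[["ankle"]] * L, 0.07)
  R2 <- footkinetics:::rot2cw(m$progression_angle)
  jc_g <- c(as.vector(R2 %*% jc_foot[1:2]) + m$foot_position, jc_foot[3])
  q <- field_quadrature(m, s, pitch = 0.001)
  M_q <- q$moment_about(jc_g)
  k <- round(s) + 1
  # reconstruct the global moment from the GT CoP/force at that station
  f <- gt$forces$ankle[k]
  cop <- gt$cops$ankle[which.min(abs(s_grid - s)), ]
  M_cf <- joint_moment(f, cop, jc_g)
  expect_lt(max(abs(M_q - M_cf)) / max(abs(M_cf)), 0.001)
})

test_that("doubling blob amplitudes doubles every ground-truth moment", {
  m <- fast_model(seed = 56, noise_sd = 0)
  gt1 <- ground_truth_kinetics(m)
  m2 <- m
  m2$force_profile$peaks <- 2 * m$force_profile$peaks
  m2$force_profile$valley <- 2 * m$force_profile$valley
  gt2 <- ground_truth_kinetics(m2)
  for (j in c("ankle", "mt", "mp"))
    expect_equal(gt2$moments[[j]], 2 * gt1$moments[[j]], tolerance = 1e-9)
})

test_that("saturation is flagged when the field exceeds the sensing range", {
  m <- fast_model(seed = 57, noise_sd = 0, body_mass = 160)
  m$blobs$sx <- m$blobs$sx / 2.5
  m$blobs$sy <- m$blobs$sy / 2.5
  sim <- simulate_trial(m)
  expect_true(any(sim$trial$platform$saturated_mask))
  expect_equal(max(sim$trial$platform$frames), 1000)
})

test_that("device pair with no insole bias agrees to discretization error", {
  pair <- make_device_pair(fast_model(seed = 58, noise_sd = 0), insole_bias = 1)
  fit_p <- quiet_fit(pair$platform, "platform")
  fit_i <- quiet_fit(pair$insole, "insole")
  for (j in c("ankle", "mt")) {
    fp <- max(fit_p$forces[[j]]); fi <- max(fit_i$forces[[j]])
    expect_lt(abs(fi - fp) / fp, 0.03)
  }
  # the hallux segment is bounded by the MP cut through the forefoot blob's
  # tail, where whole 10 mm platform cells flip sides; ~pitch/2 of boundary
  # mass, measured at ~4%
  expect_lt(abs(max(fit_i$forces$mp) - max(fit_p$forces$mp)) /
              max(fit_p$forces$mp), 0.05)
  for (j in c("ankle", "mt")) {
    mp_ <- max(fit_p$moments[[j]]$values[, "dfpf"])
    mi_ <- max(fit_i$moments[[j]]$values[, "dfpf"])
    expect_lt(abs(mi_ - mp_) / mp_, 0.03)
  }
  # MP joint: the one-insole-pitch registration tolerance (5.06 mm) acts on a
  # ~33 mm lever arm, so discretization admits up to ~15%; observed ~4-8%
  mp_p <- max(fit_p$moments$mp$values[, "dfpf"])
  mp_i <- max(fit_i$moments$mp$values[, "dfpf"])
  expect_lt(abs(mp_i - mp_p) / mp_p, 0.08)
})

test_that("a 10% insole bias appears as a ~10% ankle peak difference", {
  pair <- make_device_pair(fast_model(seed = 59, noise_sd = 0), insole_bias = 0.9)
  fit_p <- quiet_fit(pair$platform, "platform")
  fit_i <- quiet_fit(pair$insole, "insole")
  diff_pct <- 100 * (max(fit_p$moments$ankle$values[, "dfpf"]) -
                       max(fit_i$moments$ankle$values[, "dfpf"])) /
    max(fit_p$moments$ankle$values[, "dfpf"])
  expect_lt(abs(diff_pct - 10), 3)
})

test_that("parameter recovery error grows with sensor noise", {
  errs <- sapply(c(0, 10, 30), function(ns) {
    sim <- simulate_trial(fast_model(seed = 60, noise_sd = ns))
    fit <- quiet_fit(sim$trial, "platform")
    gt_pk <- max(sim$ground_truth$moments$ankle[, "dfpf"])
    abs(max(fit$moments$ankle$values[, "dfpf"]) - gt_pk) / gt_pk
  })
  expect_lt(errs[1], errs[3])
})
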