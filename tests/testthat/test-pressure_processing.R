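test_that("frame force and CoP match hand-computed values", {
  g <- grid_geometry(1, 1, 0.01, 0.01, origin = c(0.05, 0.10))
  ff <- frame_force_cop(matrix(100), g)
  expect_equal(ff$f_normal, 10)                       # 100 kPa over 1 cm^2
  expect_equal(ff$cop, c(0.05, 0.10))

  g2 <- grid_geometry(2, 1, 0.01, 0.01, origin = c(0, 0))   # cells at y = 0, 0.01
  ff2 <- frame_force_cop(matrix(c(100, 100), 2, 1), g2)
  expect_equal(ff2$cop[2], 0.005)

  ff3 <- frame_force_cop(matrix(c(100, 300), 2, 1), g2)
  expect_equal(ff3$f_normal, 40)
  expect_equal(ff3$cop[2], 0.0075)                    # pressure-weighted mean

  ff0 <- frame_force_cop(matrix(c(0, 0), 2, 1), g2)
  expect_equal(ff0$f_normal, 0)
  expect_true(all(is.na(ff0$cop)))
})

test_that("CoP lies in the convex hull of active cells on random frames", {
  set.seed(21)
  g <- tiny_geometry(6, 6)
  centers <- cell_centers(g)
  for (i in 1:50) {
    fr <- matrix(0, 6, 6)
    k <- sample(36, sample(1:10, 1))
    fr[k] <- runif(length(k), 4, 800)
    ff <- frame_force_cop(fr, g)
    expect_true(in_convex_hull(ff$cop, centers[k, , drop = FALSE], tol = 1e-9))
  }
})

test_that("stance detection finds the longest qualifying run", {
  expect_equal(unname(detect_stance(c(0, 0, 50, 80, 60, 0), 10, 2)), c(3L, 5L))
  expect_error(detect_stance(rep(0, 20), 10, 3),
               class = "footkinetics_no_stance_error")
  # short spike before the true stance is ignored
  f <- c(0, 30, 0, rep(0, 3), rep(100, 40), 0)
  expect_equal(unname(detect_stance(f, 10, 3)), c(7L, 46L))

  sim <- simulate_trial(fast_model(seed = 22))
  st <- detect_stance(total_force(sim$trial$platform),
                      stance_threshold(sim$trial$meta$body_mass))
  expect_lte(abs(st[1] - sim$stance_frames["onset"]), 2)
  expect_lte(abs(st[2] - sim$stance_frames["offset"]), 2)
})

test_that("cell segmentation follows the half-open anteroposterior rule", {
  g <- grid_geometry(1, 1, 0.01, 0.01, origin = c(0, 0.18))
  jc <- c(mt = 0.15, mp = 0.22)
  m <- segment_cells(matrix(200), g, jc)
  expect_true(m$forefoot[1, 1]); expect_false(m$hallux[1, 1])

  g_mt <- grid_geometry(1, 1, 0.01, 0.01, origin = c(0, 0.15))
  m2 <- segment_cells(matrix(200), g_mt, jc)
  expect_true(m2$forefoot[1, 1])        # boundary cell goes distal
  expect_false(m2$hindfoot[1, 1])

  g_hx <- grid_geometry(1, 1, 0.01, 0.01, origin = c(0, 0.25))
  expect_true(segment_cells(matrix(200), g_hx, jc)$hallux[1, 1])

  expect_error(segment_cells(matrix(200), g, c(mt = 0.22, mp = 0.15)),
               class = "footkinetics_validation_error")
})

test_that("segment masks partition active cells and forces are conserved", {
  set.seed(23)
  g <- tiny_geometry(8, 5, origin = c(-0.02, 0))
  for (i in 1:30) {
    fr <- matrix(0, 8, 5)
    k <- sample(40, 12)
    fr[k] <- runif(12, 4, 900)
    jc <- sort(runif(2, 0.005, 0.065))
    masks <- segment_cells(fr, g, c(mt = jc[1], mp = jc[2]))
    tot <- masks$hindfoot + masks$forefoot + masks$hallux
    expect_true(all(tot[fr > 0] == 1))
    expect_true(all(tot[fr == 0] == 0))
    area <- g$pitch_x * g$pitch_y
    f_seg <- sum(fr[masks$hindfoot]) + sum(fr[masks$forefoot]) + sum(fr[masks$hallux])
    expect_identical(f_seg * 1000 * area, sum(fr) * 1000 * area)
  }
})

test_that("rigid transforms invert exactly", {
  set.seed(24)
  for (i in 1:20) {
    tf <- rigid_transform2d(runif(1, -pi, pi), rnorm(2, 0, 0.1))
    pts <- matrix(rnorm(20), 10, 2)
    back <- apply_transform(tf, apply_transform(tf, pts), inverse = TRUE)
    expect_equal(back, pts, tolerance = 1e-12)
  }
})

test_that("registration recovers the generating transform", {
  # identity case: insole CoP already equals platform CoP, foot angle 0
  m0 <- fast_model(seed = 25, progression_angle = 0, foot_position = c(0, 0),
                   noise_sd = 0)
  sim0 <- simulate_trial(m0)
  st <- detect_stance(total_force(sim0$trial$platform), stance_threshold(71))
  tf0 <- register_insole(sim0$trial$insole, sim0$trial$platform,
                         sim0$trial$markers, st[1])
  expect_equal(tf0$theta, 0, tolerance = 1e-12)
  expect_lt(sqrt(sum(tf0$t^2)), 0.006)     # within one insole pitch

  # known transform: theta = 10 deg, t = (0.03, -0.01); rotation from the
  # (noiseless) markers is exact, translation limited by CoP discretization
  m <- fast_model(seed = 26, progression_angle = 10 * pi / 180,
                  foot_position = c(0.03, -0.01), noise_sd = 0)
  sim <- simulate_trial(m)
  st <- detect_stance(total_force(sim$trial$platform), stance_threshold(71))
  tf <- register_insole(sim$trial$insole, sim$trial$platform,
                        sim$trial$markers, st[1])
  expect_equal(tf$theta, 10 * pi / 180, tolerance = 1e-9)
  expect_lt(max(abs(tf$t - c(0.03, -0.01))), sim$trial$insole$geometry$pitch_y)

  # post-registration CoP trajectories agree within one insole pitch (RMS)
  sf_p <- segmented_forces(sim$trial$platform,
                           list(mt = joint_center(sim$trial$markers, "mt"),
                                mp = joint_center(sim$trial$markers, "mp")),
                           st, sim$trial$markers)
  tfm <- register_insole(sim$trial$insole, sim$trial$platform,
                         sim$trial$markers, st[1])
  sf_i <- segmented_forces(sim$trial$insole,
                           list(mt = joint_center(sim$trial$markers, "mt"),
                                mp = joint_center(sim$trial$markers, "mp")),
                           st, sim$trial$markers, transform = tfm)
  d <- sf_p$cop$ankle - sf_i$cop$ankle
  rms <- sqrt(mean(rowSums(d^2), na.rm = TRUE))
  # the trajectory mismatch is dominated by the coarser (platform) grid
  expect_lt(rms, sim$trial$platform$geometry$pitch_y)
})

test_that("registration fails cleanly without force at the matching instant", {
  sim <- simulate_trial(fast_model(seed = 27))
  expect_error(register_insole(sim$trial$insole, sim$trial$platform,
                               sim$trial$markers, onset = 1L),
               class = "footkinetics_registration_error")
})

test_that("segmented forces nest and the ankle equals the frame total", {
  sim <- simulate_trial(fast_model(seed = 28))
  tr <- sim$trial
  st <- detect_stance(total_force(tr$platform), stance_threshold(tr$meta$body_mass))
  jt <- list(mt = joint_center(tr$markers, "mt"),
             mp = joint_center(tr$markers, "mp"))
  sf <- segmented_forces(tr$platform, jt, st, tr$markers)
  expect_true(all(sf$f$mp <= sf$f$mt + 1e-12))
  expect_true(all(sf$f$mt <= sf$f$ankle + 1e-12))
  tot <- total_force(tr$platform)[st[1]:st[2]]
  expect_equal(sf$f$ankle, tot, tolerance = 1e-12)
})

test_that("heel-only pressure loads the ankle but not MT or MP", {
  m <- fast_model(seed = 29)
  # a frame with all pressure behind the MT joint
  g <- tiny_geometry(4, 3, origin = c(-0.01, 0))
  fr <- matrix(0, 4, 3); fr[1, 2] <- 300
  masks <- segment_cells(fr, g, c(mt = 0.05, mp = 0.08))
  expect_true(masks$hindfoot[1, 2])
  expect_equal(sum(masks$forefoot) + sum(masks$hallux), 0L)
})
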