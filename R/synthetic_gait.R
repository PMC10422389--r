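# Synthetic gait trials: one continuous plantar-pressure field sampled by
# both sensor grids, plus rigid-foot marker trajectories, with exact
# (closed-form) ground-truth segmented forces and joint moments.
#
# The field is a time-varying mixture of three 2D Gaussian loading blobs
# (heel, metatarsal heads, hallux) whose weights shift heel-to-toe across the
# stance, scaled by a double-hump vertical ground-reaction-force profile.
# Gaussians make every segment integral available in closed form (truncated-
# normal moments), so the ground truth is exact, not merely finely sampled.

#' Specify a synthetic gait trial
#'
#' Defaults describe a typical adult walking trial: 0.7 s stance at 100 Hz,
#' body mass 71 kg, 0.25 m foot, vertical GRF peaks of 1.1 and 1.05 body
#' weight at 25% and 75% stance with a 0.8 body-weight valley.
#'
#' @param foot_length foot length (m).
#' @param joint_fractions named fractions of foot length (from the heel) of
#'   the ankle, midtarsal and metatarsophalangeal joint axes; must be
#'   strictly increasing in (0, 1).
#' @param body_mass body mass (kg).
#' @param stance_duration stance time (s).
#' @param rate sampling rate (Hz).
#' @param force_profile list with `peaks` (body weights), `peak_times`
#'   (% stance) and `valley` (body weight at mid-stance).
#' @param blobs loading-blob table; see [default_blobs()].
#' @param progression_angle foot toe-out angle (rad).
#' @param foot_position global 2D position of the heel (m).
#' @param platform_pitch platform cell pitch (m; default 10 mm = 1
#'   sensel/cm^2). The 0.4 m platform is re-gridded accordingly.
#' @param insole_pitch insole cell pitch (m; default 5.06 mm ~ 3.9
#'   sensels/cm^2).
#' @param noise_sd additive pressure noise per loaded cell (kPa).
#' @param insole_bias multiplicative factor on the field sampled by the
#'   insole (1 = both devices see the same field; < 1 models the insole's
#'   incomplete capture of contact forces).
#' @param lead zero-force lead-in/out recorded around the stance (s).
#' @param seed integer seed; all stochastic draws flow from it.
#' @return An object of class `gait_model`.
#' @export
gait_model <- function(foot_length = 0.25,
                       joint_fractions = c(ankle = 0.25, mt = 0.45, mp = 0.75),
                       body_mass = 71,
                       stance_duration = 0.7,
                       rate = 100,
                       force_profile = list(peaks = c(1.1, 1.05),
                                            peak_times = c(25, 75),
                                            valley = 0.8),
                       blobs = default_blobs(foot_length),
                       progression_angle = 0.08,
                       foot_position = c(0.02, -0.11),
                       platform_pitch = 0.01,
                       insole_pitch = 0.00506,
                       noise_sd = 2,
                       insole_bias = 1,
                       lead = 0.15,
                       seed = 1L) {
  jf <- joint_fractions
  if (!all(c("ankle", "mt", "mp") %in% names(jf)) ||
      any(jf <= 0) || any(jf >= 1) ||
      is.unsorted(jf[c("ankle", "mt", "mp")], strictly = TRUE))
    abort("joint fractions must satisfy 0 < ankle < MT < MP < 1", "validation_error")
  if (body_mass <= 0 || stance_duration <= 0 || rate <= 0 || foot_length <= 0)
    abort("model scalars must be positive", "validation_error")
  if (insole_bias <= 0) abort("insole_bias must be positive", "validation_error")
  if (platform_pitch <= 0 || insole_pitch <= 0)
    abort("grid pitches must be positive", "validation_error")
  if (noise_sd < 0) abort("noise_sd must be non-negative", "validation_error")
  structure(list(foot_length = foot_length, joint_fractions = jf,
                 body_mass = body_mass, stance_duration = stance_duration,
                 rate = rate, force_profile = force_profile, blobs = blobs,
                 progression_angle = progression_angle,
                 foot_position = as.numeric(foot_position),
                 platform_pitch = platform_pitch, insole_pitch = insole_pitch,
                 noise_sd = noise_sd, insole_bias = insole_bias,
                 lead = lead, seed = as.integer(seed)),
            class = "gait_model")
}

#' Default loading blobs of the synthetic pressure field
#'
#' Three Gaussian loading centers in the foot frame (heel, metatarsal heads,
#' hallux): positions as fractions of the foot length along the axis, widths
#' in meters. Weight curves shift smoothly from heel-dominant at contact to
#' hallux/metatarsal-dominant before toe-off.
#'
#' @param foot_length foot length (m).
#' @return Data frame with one row per blob.
#' @export
default_blobs <- function(foot_length = 0.25) {
  data.frame(name = c("heel", "met", "hallux"),
             cx = c(0.002, -0.010, -0.010),
             cy = foot_length * c(0.15, 0.70, 0.88),
             sx = c(0.018, 0.020, 0.011),
             sy = c(0.020, 0.015, 0.012))
}

# blob mixture weights at % stance s (vectorized over s); rows = blobs
blob_weights <- function(s) {
  wh <- 1 / (1 + exp((s - 40) / 7))
  wm <- 1 / (1 + exp(-(s - 30) / 8)) / (1 + exp((s - 90) / 6))
  wx <- 0.45 / (1 + exp(-(s - 72) / 6))
  w <- rbind(heel = wh, met = wm, hallux = wx)
  sweep(w, 2L, colSums(w), "/")
}

# vertical GRF profile (N) as a function of % stance: half-cosine segments
# between the configured extremes (zero slope at every knot, so the peaks and
# valley are attained exactly with no interpolation overshoot)
grf_profile <- function(model) {
  fp <- model$force_profile
  bw <- model$body_mass * 9.81
  ks <- c(0, fp$peak_times[1L], 50, fp$peak_times[2L], 100)
  kf <- c(0, fp$peaks[1L], fp$valley, fp$peaks[2L], 0) * bw
  function(s) {
    s <- pmin(pmax(s, 0), 100)
    seg <- pmin(findInterval(s, ks, rightmost.closed = TRUE), length(ks) - 1L)
    u <- (s - ks[seg]) / (ks[seg + 1L] - ks[seg])
    kf[seg] + (kf[seg + 1L] - kf[seg]) * (1 - cos(pi * u)) / 2
  }
}

# continuous pressure field in kPa at foot-frame points (n x 2), one instant
field_kpa <- function(pts, s, model, F = NULL) {
  if (is.null(F)) F <- grf_profile(model)(s)
  if (F <= 0) return(numeric(nrow(pts)))
  w <- blob_weights(s)[, 1L]
  b <- model$blobs
  dens <- 0
  for (k in seq_len(nrow(b))) {
    dens <- dens + w[k] *
      stats::dnorm(pts[, 1L], b$cx[k], b$sx[k]) *
      stats::dnorm(pts[, 2L], b$cy[k], b$sy[k])
  }
  F * dens / 1000                     # Pa -> kPa
}

#' Foot-frame marker layout of the synthetic rigid foot
#'
#' @param model a [gait_model()].
#' @return Named list of 3D foot-frame positions (m): heel at the origin,
#'   long axis +y, up +z. Markers C1 and H2 lie exactly on the long axis so
#'   the foot progression angle recovered from them is exact.
#' @export
marker_layout <- function(model) {
  L <- model$foot_length
  aL <- model$joint_fractions[["ankle"]] * L
  mtL <- model$joint_fractions[["mt"]] * L
  mpL <- model$joint_fractions[["mp"]] * L
  list(C1 = c(0, 0, 0.02), C2 = c(0, 0.02, 0.06),
       MC = c(-0.04, aL, 0.07), LC = c(0.04, aL, 0.07),
       NV = c(-0.03, mtL, 0.04), CU = c(0.03, mtL, 0.035),
       B1 = c(-0.03, 0.50 * L, 0.035), B5 = c(0.035, 0.50 * L, 0.03),
       H1 = c(-0.035, mpL, 0.03), H3 = c(0.035, mpL, 0.03),
       H2 = c(0, 0.80 * L, 0.035), HX = c(0, 0.93 * L, 0.025),
       SH1 = c(-0.04, aL, 0.35), SH2 = c(0.04, aL, 0.35),
       SH3 = c(-0.04, aL, 0.15), SH4 = c(0.04, aL, 0.15))
}

place_markers <- function(layout, theta, t, n_frames, rate) {
  R <- rot2cw(theta)
  pos <- lapply(layout, function(p) {
    xy <- as.vector(R %*% p[1:2]) + t
    matrix(rep(c(xy, p[3L]), each = n_frames), n_frames, 3L)
  })
  marker_set(pos, rate)
}

stance_percents <- function(model) {
  n_st <- as.integer(round(model$stance_duration * model$rate)) + 1L
  seq(0, 100, length.out = n_st)
}

#' Simulate a synchronized gait trial with exact ground truth
#'
#' Samples the continuous pressure field on the platform grid (10 mm pitch,
#' global frame) and the insole grid (5.06 mm pitch, foot frame), adds
#' truncated Gaussian sensor noise, clips to each device's sensing range, and
#' places the rigid-foot markers. The output is bitwise reproducible for a
#' given model (seeded internally).
#'
#' @param model a [gait_model()].
#' @param meta optional [trial_meta()]; defaults to subject "S1", shoe "A",
#'   trial 1 with the model's body mass.
#' @return List with `trial` (a [gait_trial()]) and `ground_truth`
#'   (see [ground_truth_kinetics()]).
#' @export
simulate_trial <- function(model, meta = NULL) {
  stopifnot(inherits(model, "gait_model"))
  if (is.null(meta))
    meta <- trial_meta("S1", model$body_mass, "A", "platform", 1L)
  rate <- model$rate
  n_lead <- as.integer(round(model$lead * rate))
  s_grid <- stance_percents(model)
  n_st <- length(s_grid)
  nf <- n_st + 2L * n_lead
  Fs <- grf_profile(model)(s_grid)

  pp <- model$platform_pitch
  np <- as.integer(round(0.4 / pp))
  plat_geom <- grid_geometry(np, np, pp, pp,
                             origin = rep(-(np - 1) / 2 * pp, 2L), orientation = 0,
                             frame_of_reference = "global")
  ip <- model$insole_pitch
  n_ir <- as.integer(ceiling((model$foot_length + 0.004) / ip))
  n_ic <- as.integer(ceiling(0.111 / ip))
  ins_geom <- grid_geometry(n_ir, n_ic, ip, ip,
                            origin = c(-(n_ic - 1) / 2 * ip, 0.001), orientation = 0,
                            frame_of_reference = "foot")

  theta <- model$progression_angle
  tpos <- model$foot_position
  plat_centers_foot <- sweep(cell_centers(plat_geom), 2L, tpos, "-") %*% rot2cw(theta)
  ins_centers <- cell_centers(ins_geom)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(model$seed)

  plat_arr <- array(0, c(plat_geom$n_rows, plat_geom$n_cols, nf))
  ins_arr <- array(0, c(ins_geom$n_rows, ins_geom$n_cols, nf))
  for (k in seq_len(n_st)) {
    i <- n_lead + k
    plat_arr[, , i] <- field_kpa(plat_centers_foot, s_grid[k], model, Fs[k])
    ins_arr[, , i] <- model$insole_bias *
      field_kpa(ins_centers, s_grid[k], model, Fs[k])
  }
  if (model$noise_sd > 0) {
    # pressure-cell noise is load-modulated: unloaded cells read zero
    loaded_p <- plat_arr > 0.1
    loaded_i <- ins_arr > 0.1
    plat_arr[loaded_p] <- pmax(plat_arr[loaded_p] +
      stats::rnorm(sum(loaded_p), 0, model$noise_sd), 0)
    ins_arr[loaded_i] <- pmax(ins_arr[loaded_i] +
      stats::rnorm(sum(loaded_i), 0, model$noise_sd), 0)
  }

  markers <- place_markers(marker_layout(model), theta, tpos, nf, rate)
  static <- place_markers(marker_layout(model), 0, c(0, -0.125), 10L, rate)

  trial <- gait_trial(meta, markers,
                      pressure_sequence(plat_arr, plat_geom, rate, "platform"),
                      pressure_sequence(ins_arr, ins_geom, rate, "insole"),
                      static)
  list(trial = trial, ground_truth = ground_truth_kinetics(model),
       stance_frames = c(onset = n_lead + 1L, offset = n_lead + n_st))
}

# distal (>= boundary) mass fraction and truncated CoP of one Gaussian blob
blob_distal <- function(b, boundary) {
  if (boundary == -Inf) {
    list(q = 1, cy = b$cy)
  } else {
    alpha <- (boundary - b$cy) / b$sy
    q <- stats::pnorm(alpha, lower.tail = FALSE)
    cy <- if (q < 1e-300) boundary else
      b$cy + b$sy * stats::dnorm(alpha) / q
    list(q = q, cy = cy)
  }
}

#' Exact ground-truth segmented forces and joint moments of a model
#'
#' Evaluates the continuous pressure field analytically: segment integrals
#' and centers of pressure are truncated-normal moments of the Gaussian
#' blobs, so the ground truth carries no discretization error. Moments follow
#' the pipeline's conventions (normal forces only, proximal-segment
#' components, body-weight normalization, 101-point stance grid), with
#' proximal frames built from the exact marker layout.
#'
#' @param model a [gait_model()].
#' @return List with `forces` (per-joint 101-sample N curves), `cops`
#'   (per-joint 101 x 2 global CoP tracks), `moments` (per-joint 101 x 3
#'   matrices, columns dfpf/abad/inev, N.m/kg) and `params` (peak
#'   descriptors per joint and motion).
#' @export
ground_truth_kinetics <- function(model) {
  s_grid <- stance_percents(model)
  n_st <- length(s_grid)
  Fs <- grf_profile(model)(s_grid)
  W <- blob_weights(s_grid)
  b <- model$blobs
  L <- model$foot_length
  bounds <- c(ankle = -Inf, mt = model$joint_fractions[["mt"]] * L,
              mp = model$joint_fractions[["mp"]] * L)
  theta <- model$progression_angle; tpos <- model$foot_position
  R2 <- rot2cw(theta)

  layout <- marker_layout(model)
  static_ms <- place_markers(layout, theta, tpos, 2L, model$rate)
  recipes <- default_recipes()
  prox_of <- c(ankle = "shank", mt = "hindfoot", mp = "forefoot")
  prox_R <- lapply(unique(prox_of), function(s)
    build_segment_frame(static_ms, recipes[[s]], 1L)$rotation)
  names(prox_R) <- unique(prox_of)
  jc_global <- lapply(c(ankle = "ankle", mt = "mt", mp = "mp"), function(j) {
    pr <- default_joint_pairs()[[j]]
    p <- (layout[[pr[1L]]] + layout[[pr[2L]]]) / 2
    c(as.vector(R2 %*% p[1:2]) + tpos, p[3L])
  })

  forces <- list(); cops <- list(); moments <- list()
  for (j in names(bounds)) {
    f <- numeric(n_st); cop <- matrix(NA_real_, n_st, 2L); M <- matrix(0, n_st, 3L)
    for (k in seq_len(n_st)) {
      qs <- cys <- numeric(nrow(b))
      for (i in seq_len(nrow(b))) {
        d <- blob_distal(b[i, ], bounds[[j]])
        qs[i] <- W[i, k] * d$q
        cys[i] <- d$cy
      }
      fk <- Fs[k] * sum(qs)
      f[k] <- fk
      if (fk > 1e-9) {
        cop_foot <- c(sum(qs * b$cx), sum(qs * cys)) / sum(qs)
        cop[k, ] <- as.vector(R2 %*% cop_foot) + tpos
        M[k, ] <- joint_moment(fk, cop[k, ], jc_global[[j]],
                               prox_R[[prox_of[[j]]]])
      }
    }
    forces[[j]] <- resample_stance(f, 1L, n_st, 101L)
    cops[[j]] <- cop
    local_m <- cbind(dfpf = M[, 1L], abad = M[, 3L], inev = M[, 2L]) /
      model$body_mass
    moments[[j]] <- apply(local_m, 2L, resample_stance, onset = 1L,
                          offset = n_st, n = 101L)
  }
  params <- do.call(rbind, lapply(names(moments), function(j) {
    rbind(
      do.call(rbind, lapply(colnames(moments[[j]]), function(m) {
        p <- extract_params(moments[[j]][, m])
        data.frame(joint = j, motion = m,
                   parameter = c("MaxVal", "TMax", "MinVal", "TMin"),
                   value = c(p$max_val, p$t_max, p$min_val, p$t_min))
      })),
      { p <- extract_params(forces[[j]])
        data.frame(joint = j, motion = "force",
                   parameter = c("MaxVal", "TMax"),
                   value = c(p$max_val, p$t_max)) })
  }))
  list(forces = forces, cops = cops, moments = moments, params = params)
}

#' Ground-truth moment curves of a model
#'
#' @param model a [gait_model()].
#' @return Named list (ankle, mt, mp) of 101 x 3 moment matrices (N.m/kg).
#' @export
ground_truth_moments <- function(model) ground_truth_kinetics(model)$moments

#' Brute-force quadrature of the continuous field (refinement oracle)
#'
#' Integrates the field on a fine regular grid over the foot, independently
#' of the closed-form ground truth: used to cross-check it.
#'
#' @param model a [gait_model()].
#' @param s % stance instant.
#' @param boundary foot-frame along-axis coordinate below which cells are
#'   dropped (`-Inf` = whole foot).
#' @param pitch quadrature pitch (m, default 1 mm).
#' @return List `f` (N), `cop` (foot frame, m) and `moment_about`
#'   (function of a global 3D joint center returning the global moment).
#' @export
field_quadrature <- function(model, s, boundary = -Inf, pitch = 0.001) {
  xs <- seq(-0.12, 0.12, by = pitch)
  ys <- seq(-0.10, model$foot_length + 0.12, by = pitch)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  keep <- pts[, 2L] >= boundary
  pts <- pts[keep, , drop = FALSE]
  p <- field_kpa(pts, s, model)
  w <- p * 1000 * pitch^2
  f <- sum(w)
  cop <- as.vector(crossprod(pts, w)) / f
  R2 <- rot2cw(model$progression_angle)
  pts_g <- pts %*% t(R2) + matrix(model$foot_position, nrow(pts), 2L, byrow = TRUE)
  list(f = f, cop = cop,
       moment_about = function(jc) {
         # vertical cell forces: the jc height drops out of the cross product
         dx <- pts_g[, 1L] - jc[1L]; dy <- pts_g[, 2L] - jc[2L]
         c(sum(dy * w), -sum(dx * w), 0)
       })
}

#' Simulate the two-device comparison pair
#'
#' Returns one trial per analysis device built from the same field and the
#' same random draws; the insole stream is scaled by `insole_bias`, modeling
#' the insole's incomplete capture of contact forces.
#'
#' @param model a [gait_model()].
#' @param insole_bias multiplicative insole factor (> 0).
#' @return List with `platform` and `insole` [gait_trial()] objects and the
#'   shared `ground_truth`.
#' @export
make_device_pair <- function(model, insole_bias = 1) {
  if (insole_bias <= 0) abort("insole_bias must be positive", "validation_error")
  model$insole_bias <- insole_bias
  sim <- simulate_trial(model)
  t_p <- sim$trial
  t_i <- sim$trial
  t_p$meta$device <- "platform"
  t_i$meta$device <- "insole"
  list(platform = t_p, insole = t_i, ground_truth = sim$ground_truth)
}
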