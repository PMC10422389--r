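# External joint moments from segmented normal contact forces.
#
# Only the normal (vertical) component of the contact force enters: friction
# is not measured by pressure devices, and segment weight/inertia are
# neglected, so the moment about a joint is the cross product of the lever
# arm from the joint center to the (ground-plane) CoP with the vertical
# resultant of the cells distal to the joint.

#' External joint moment from a resultant force and CoP
#'
#' `M_global = (cop_3d - jc) x F` with `F = (0, 0, f_normal)` and the CoP
#' lifted to the ground plane `z = 0`; the moment is then expressed in the
#' proximal-segment frame by `t(proximal_rotation) %*% M_global`.
#'
#' @param f_normal resultant normal force (N).
#' @param cop 2D ground-plane CoP (m, global).
#' @param jc 3D joint center (m, global).
#' @param proximal_rotation 3x3 local-to-global rotation of the proximal
#'   segment (default identity = global components).
#' @return Numeric 3-vector, moment in the proximal frame (N.m), components
#'   along the proximal (x, y, z) axes.
#' @export
joint_moment <- function(f_normal, cop, jc, proximal_rotation = diag(3)) {
  if (max(abs(crossprod(proximal_rotation) - diag(3))) > 1e-6)
    abort("proximal_rotation is not orthonormal", "validation_error")
  if (f_normal == 0) return(c(0, 0, 0))
  r <- c(cop[1L], cop[2L], 0) - jc
  M <- cross3(r, c(0, 0, f_normal))
  as.vector(crossprod(proximal_rotation, M))
}

#' Per-cell moment sum (independent verification oracle)
#'
#' Brute-force global moment of a masked pressure frame about a joint center:
#' `M = sum_i (r_i - jc) x (0, 0, p_i * A_i)`. For parallel (vertical) cell
#' forces this equals [joint_moment()] computed from the mask's resultant and
#' CoP exactly; the test suite checks the identity numerically.
#'
#' @param frame pressure matrix (kPa).
#' @param geometry grid geometry.
#' @param mask logical matrix of cells to include.
#' @param jc 3D joint center (m).
#' @param centers optional global cell centers.
#' @return Numeric 3-vector, global moment (N.m).
#' @export
per_cell_moment_oracle <- function(frame, geometry, mask, jc, centers = NULL) {
  if (is.null(centers)) centers <- cell_centers(geometry)
  w <- as.vector(frame) * 1000 * geometry$pitch_x * geometry$pitch_y
  w <- w * as.vector(mask)
  M <- c(0, 0, 0)
  for (i in which(w != 0))
    M <- M + cross3(c(centers[i, 1L], centers[i, 2L], 0) - jc, c(0, 0, w[i]))
  M
}

#' Body-weight normalization of a moment
#'
#' @param m moment (N.m), vector or matrix.
#' @param mass body mass (kg, > 0).
#' @return `m / mass` (N.m/kg).
#' @export
normalize_moment <- function(m, mass) {
  if (!is_scalar_num(mass) || mass <= 0)
    abort("mass must be positive", "validation_error")
  m / mass
}

# effective kinetic cutoff after Nyquist clipping, warning once
effective_cutoff <- function(fc, fs) {
  nyq <- fs / 2
  if (fc >= nyq) {
    warnf("kinetic cutoff %g Hz is at/above Nyquist (%g Hz); clipped to %g Hz",
          fc, nyq, 0.95 * nyq)
    fc <- 0.95 * nyq
  }
  fc
}

#' Joint moment curves of one trial
#'
#' Runs the kinetic pipeline for one device of a trial: marker low-pass
#' (10 Hz default), stance detection on the device's total force, insole
#' registration where needed, per-frame cell segmentation and distal
#' resultants, per-frame moments in the proximal-segment frame, kinetic
#' low-pass, body-weight normalization and resampling to 0..100% stance.
#' Component order is (dfpf, abad, inev): flexion about the proximal x axis,
#' abduction about z, inversion about y.
#'
#' @param trial a [gait_trial()].
#' @param device `"platform"` or `"insole"`.
#' @param config a [pipeline_config()].
#' @return List of class `moment_curve_set`: per-joint `moment_curve` objects
#'   (`values` 101 x 3, N.m/kg), plus `forces` (per-joint 101-sample N
#'   curves), `stance`, `transform`.
#' @export
moment_curves <- function(trial, device = c("platform", "insole"),
                          config = pipeline_config()) {
  device <- match.arg(device)
  seq <- trial[[device]]
  rate <- seq$rate

  markers <- trial$markers
  if (isTRUE(config$gap_fill)) markers <- fill_gaps(markers, config$max_gap)
  if (any(vapply(markers$positions, anyNA, logical(1))))
    abort("markers contain missing samples; enable gap filling or repair upstream",
          "validation_error")
  mk_f <- filter_markers(markers, config$kinematic_cutoff)

  thr <- config$stance_threshold %||% stance_threshold(trial$meta$body_mass)
  stance <- detect_stance(total_force(seq), thr, config$min_stance_frames)
  dur <- (stance[2L] - stance[1L]) / rate
  if (dur < config$min_stance_duration) {
    warnf("stance of %.2f s is shorter than %.2f s; trial rejected",
          dur, config$min_stance_duration)
    abort("stance too short; trial invalid", "trial_rejected_error")
  }

  transform <- NULL
  if (device == "insole") {
    onset_p <- detect_stance(total_force(trial$platform), thr,
                             config$min_stance_frames)[1L]
    transform <- register_insole(trial$insole, trial$platform, mk_f, onset_p,
                                 config$registration_delay)
  }

  jc_tracks <- list(ankle = joint_center(mk_f, "ankle", config$joint_pairs$ankle),
                    mt = joint_center(mk_f, "mt", config$joint_pairs$mt),
                    mp = joint_center(mk_f, "mp", config$joint_pairs$mp))
  sf <- segmented_forces(seq, jc_tracks, stance, mk_f,
                         axis_mode = config$segmentation_axis, transform = transform)

  prox_of <- c(ankle = "shank", mt = "hindfoot", mp = "forefoot")
  prox_frames <- lapply(unique(prox_of), function(s)
    segment_frames(mk_f, config$recipes[[s]]))
  names(prox_frames) <- unique(prox_of)

  fc_kin <- effective_cutoff(config$kinetic_cutoff, rate)
  n_out <- config$resample_n
  idx <- sf$frames
  curves <- list()
  forces <- list()
  for (j in JOINTS) {
    M <- matrix(0, length(idx), 3L)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (sf$f[[j]][k] > 0)
        M[k, ] <- joint_moment(sf$f[[j]][k], sf$cop[[j]][k, ],
                               jc_tracks[[j]]$position[i, ],
                               prox_frames[[prox_of[[j]]]]$rotation[, , i])
    }
    # local (x, y, z) moments -> motion components (dfpf, abad, inev)
    comp <- cbind(dfpf = M[, 1L], abad = M[, 3L], inev = M[, 2L])
    comp <- apply(comp, 2L, butterworth_lowpass, fs = rate, fc = fc_kin)
    comp <- normalize_moment(comp, trial$meta$body_mass)
    vals <- apply(comp, 2L, resample_stance, onset = 1L, offset = nrow(comp),
                  n = n_out)
    curves[[j]] <- structure(list(joint = j, values = vals, device = device,
                                  meta = trial$meta, units = "N.m/kg"),
                             class = "moment_curve")
    ffilt <- butterworth_lowpass(sf$f[[j]], fs = rate, fc = fc_kin)
    forces[[j]] <- resample_stance(ffilt, 1L, length(ffilt), n_out)
  }
  structure(list(moments = curves, forces = forces, stance = stance,
                 transform = transform, device = device),
            class = "moment_curve_set")
}

# low-pass every coordinate of every marker
filter_markers <- function(markers, fc) {
  pos <- lapply(markers$positions, function(p)
    apply(p, 2L, butterworth_lowpass, fs = markers$rate, fc = fc))
  marker_set(pos, markers$rate)
}
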