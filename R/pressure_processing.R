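# Pressure frames -> forces and centers of pressure; stance detection;
# insole-to-global registration; cell-to-segment assignment.

#' Resultant normal force and center of pressure of one pressure frame
#'
#' `f = sum(p_i * A_i)` with the kPa -> Pa conversion applied and
#' `A_i = pitch_x * pitch_y`; the CoP is the pressure-weighted mean of cell
#' centers. An all-zero frame yields zero force and a flagged (NA) CoP.
#'
#' @param frame `n_rows x n_cols` pressure matrix (kPa).
#' @param geometry the grid's [grid_geometry()].
#' @param centers optional precomputed [cell_centers()] (column-major order).
#' @return Object of class `frame_force`: `f_normal` (N), `cop` (2-vector, m,
#'   in the grid's frame of reference), `n_active`.
#' @export
frame_force_cop <- function(frame, geometry, centers = NULL) {
  if (nrow(frame) != geometry$n_rows || ncol(frame) != geometry$n_cols)
    abort("frame shape does not match geometry", "validation_error")
  if (is.null(centers)) centers <- cell_centers(geometry)
  area <- geometry$pitch_x * geometry$pitch_y
  p <- as.vector(frame)
  w <- p * 1000 * area                       # cell force, N
  f <- sum(w)
  if (f <= 0) {
    ff <- list(f_normal = 0, cop = c(NA_real_, NA_real_), n_active = 0L)
  } else {
    ff <- list(f_normal = f, cop = as.vector(crossprod(centers, w)) / f,
               n_active = sum(p > 0))
  }
  structure(ff, class = "frame_force")
}

# frame i of a sequence with matrix shape preserved (1 x n grids drop dims)
get_frame <- function(seq, i) {
  matrix(seq$frames[, , i], seq$geometry$n_rows, seq$geometry$n_cols)
}

#' Total normal force time series of a pressure sequence
#'
#' @param seq a [pressure_sequence()].
#' @return Numeric vector (N), one value per frame.
#' @export
total_force <- function(seq) {
  area <- seq$geometry$pitch_x * seq$geometry$pitch_y
  apply(seq$frames, 3L, sum) * 1000 * area
}

#' Default stance-detection force threshold
#'
#' The larger of 10 N and 1.5% of body weight.
#'
#' @param body_mass kg.
#' @return Threshold in N.
#' @export
stance_threshold <- function(body_mass) max(10, 0.015 * body_mass * 9.81)

#' Detect the stance interval on a total-force series
#'
#' The stance is the longest run of frames with `force > threshold` lasting at
#' least `min_frames`; returns its first and last frame.
#'
#' @param force numeric series (N).
#' @param threshold force threshold (N).
#' @param min_frames minimum run length (default 3).
#' @return Integer vector `c(onset, offset)` (1-based, inclusive).
#' @export
detect_stance <- function(force, threshold, min_frames = 3L) {
  if (length(force) < min_frames)
    abort("series shorter than min_frames", "validation_error")
  above <- force > threshold
  r <- rle(above)
  ok <- which(r$values & r$lengths >= min_frames)
  if (!length(ok)) abort("no stance interval found above threshold", "no_stance_error")
  best <- ok[which.max(r$lengths[ok])]
  ends <- cumsum(r$lengths)
  onset <- ends[best] - r$lengths[best] + 1L
  c(onset = onset, offset = ends[best])
}

#' 2D rigid transform
#'
#' Maps grid-frame points into the global frame:
#' `x_global = R(theta) x + t`, where `R(theta)` rotates the grid's long
#' (+y) axis onto a direction `theta` radians toward +X from the global
#' anterior axis -- the same sign convention as [foot_angle()].
#'
#' @param theta rotation (rad).
#' @param t 2D translation (m).
#' @return Object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(theta, t) {
  structure(list(theta = theta, t = as.numeric(t)), class = "rigid_transform2d")
}

#' Apply (or invert) a 2D rigid transform
#'
#' @param tf a [rigid_transform2d()].
#' @param pts `n x 2` matrix or 2-vector.
#' @param inverse apply the inverse transform.
#' @return Transformed points, same shape as input.
#' @export
apply_transform <- function(tf, pts, inverse = FALSE) {
  v <- is.null(dim(pts))
  pts <- rbind(pts)
  R <- rot2cw(tf$theta)
  out <- if (inverse) {
    sweep(pts, 2L, tf$t, "-") %*% R                     # R^T via right-multiplication
  } else {
    pts %*% t(R) + matrix(tf$t, nrow(pts), 2L, byrow = TRUE)
  }
  if (v) as.vector(out) else out
}

#' Register the insole grid into the global frame
#'
#' The rotation is the foot progression angle ([foot_angle()] from markers C1
#' and H2) at the matching instant, 0.1 s after initial contact; the
#' translation then superimposes the insole CoP on the platform CoP at that
#' instant. One rigid transform is held constant for the whole stance (the
#' loaded foot is quasi-static on the ground).
#'
#' @param insole insole [pressure_sequence()] (foot frame).
#' @param platform platform [pressure_sequence()] (global frame).
#' @param markers dynamic [marker_set()] with C1 and H2.
#' @param onset stance onset frame (from [detect_stance()] on the platform).
#' @param delay matching delay after onset, s (default 0.1).
#' @return A [rigid_transform2d()] mapping insole coordinates to global.
#' @export
register_insole <- function(insole, platform, markers, onset, delay = 0.1) {
  mf <- onset + as.integer(round(delay * platform$rate))
  if (mf > insole$n_frames || mf > platform$n_frames)
    abort("matching instant beyond recording", "registration_error")
  ff_i <- frame_force_cop(get_frame(insole, mf), insole$geometry)
  ff_p <- frame_force_cop(get_frame(platform, mf), platform$geometry)
  if (ff_i$f_normal <= 0 || ff_p$f_normal <= 0)
    abort("zero force on a device at the matching instant", "registration_error")
  theta <- foot_angle(marker_xyz(markers, "C1", mf), marker_xyz(markers, "H2", mf))
  t <- ff_p$cop - as.vector(rot2cw(theta) %*% ff_i$cop)
  rigid_transform2d(theta, t)
}

#' Assign active cells of one frame to foot segments
#'
#' Cells are compared with the anteroposterior (along-axis) coordinates of the
#' midtarsal and metatarsophalangeal joint centers: hindfoot behind the MT
#' coordinate, forefoot in `[MT, MP)`, hallux at or beyond MP. Intervals are
#' half-open with boundary cells going to the distal segment.
#'
#' @param frame pressure matrix (kPa).
#' @param geometry grid geometry.
#' @param jc_axis_coords named numeric, along-axis coordinates of `mt` and
#'   `mp` (and optionally `ankle`, checked for ordering).
#' @param axis unit 2D vector of the anteroposterior axis (global frame).
#' @param centers optional cell centers in the global frame (e.g. transformed
#'   insole centers).
#' @return Named list (`hindfoot`, `forefoot`, `hallux`) of logical matrices
#'   partitioning the active cells.
#' @export
segment_cells <- function(frame, geometry, jc_axis_coords, axis = c(0, 1),
                          centers = NULL) {
  jc <- jc_axis_coords
  if (!all(c("mt", "mp") %in% names(jc)))
    abort("jc_axis_coords must name mt and mp", "validation_error")
  ord <- c(jc["ankle"], jc["mt"], jc["mp"])
  ord <- ord[!is.na(ord)]
  if (is.unsorted(ord, strictly = TRUE))
    abort("joint coordinates must be ordered ankle < MT < MP along the axis",
          "validation_error")
  if (is.null(centers)) centers <- cell_centers(geometry)
  s <- as.vector(centers %*% matrix(unit(axis), 2L, 1L))
  active <- as.vector(frame) > 0
  dims <- c(geometry$n_rows, geometry$n_cols)
  list(hindfoot = matrix(active & s < jc[["mt"]], dims[1L], dims[2L]),
       forefoot = matrix(active & s >= jc[["mt"]] & s < jc[["mp"]], dims[1L], dims[2L]),
       hallux = matrix(active & s >= jc[["mp"]], dims[1L], dims[2L]))
}

#' Segmented contact forces distal to each joint over the stance
#'
#' For every stance frame, each joint's external load is the resultant of the
#' cells distal to it: all cells for the ankle, forefoot + hallux for the MT
#' joint, hallux cells for the MP joint. Nesting
#' `f(mp) <= f(mt) <= f(ankle) = total` holds by construction.
#'
#' @param seq a [pressure_sequence()] (insole sequences must come with
#'   `transform`).
#' @param jc_tracks named list of [joint_center()] tracks (`mt`, `mp` needed).
#' @param stance `c(onset, offset)` from [detect_stance()].
#' @param markers dynamic [marker_set()] (for the per-frame foot axis).
#' @param axis_mode `"foot"` (C1 -> H2 ground-plane direction, default) or
#'   `"global"` (+Y).
#' @param transform [rigid_transform2d()] placing insole cells in the global
#'   frame; required when `seq$geometry$frame_of_reference == "foot"`.
#' @return Object of class `segmented_forces`: list with `frames` (stance
#'   frame indices), per-joint `f` (N) and `cop` (`n x 2`, m global), `device`.
#' @export
segmented_forces <- function(seq, jc_tracks, stance, markers,
                             axis_mode = c("foot", "global"), transform = NULL) {
  axis_mode <- match.arg(axis_mode)
  if (seq$geometry$frame_of_reference == "foot" && is.null(transform))
    abort("insole sequence requires a registration transform", "validation_error")
  idx <- stance[1L]:stance[2L]
  centers0 <- cell_centers(seq$geometry)
  centers <- if (is.null(transform)) centers0 else apply_transform(transform, centers0)
  area <- seq$geometry$pitch_x * seq$geometry$pitch_y
  joints <- c("ankle", "mt", "mp")
  f <- sapply(joints, function(j) numeric(length(idx)), simplify = FALSE)
  cop <- sapply(joints, function(j) matrix(NA_real_, length(idx), 2L), simplify = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[k]
    fr <- get_frame(seq, i)
    axis <- if (axis_mode == "foot") {
      d <- marker_xyz(markers, "H2", i)[1:2] - marker_xyz(markers, "C1", i)[1:2]
      unit(d)
    } else c(0, 1)
    jc_ax <- c(mt = sum(jc_tracks$mt$position[i, 1:2] * axis),
               mp = sum(jc_tracks$mp$position[i, 1:2] * axis))
    masks <- segment_cells(fr, seq$geometry, jc_ax, axis, centers = centers)
    w <- as.vector(fr) * 1000 * area
    distal <- list(ankle = rep(TRUE, length(w)),
                   mt = as.vector(masks$forefoot | masks$hallux),
                   mp = as.vector(masks$hallux))
    for (j in joints) {
      wj <- w * distal[[j]]
      fj <- sum(wj)
      f[[j]][k] <- fj
      if (fj > 0) cop[[j]][k, ] <- as.vector(crossprod(centers, wj)) / fj
    }
  }
  structure(list(frames = idx, f = f, cop = cop, device = seq$device,
                 rate = seq$rate), class = "segmented_forces")
}
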