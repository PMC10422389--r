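# Segment coordinate frames, joint centers, Cardan joint angles.
#
# Local segment axes: x = flexion axis (medial-lateral), y = long axis
# (anterior), z = up. Joint rotations decompose in the order
# dorsiflexion/plantarflexion (about x), abduction/adduction (about z),
# inversion/eversion (about y), all relative to the standing static posture.

JOINTS <- c("ankle", "mt", "mp")
SEGMENTS <- c("shank", "hindfoot", "forefoot", "hallux")

#' Default segment-frame construction recipes
#'
#' Each recipe names the markers that set a segment's origin, long (anterior)
#' axis and reference plane. The long axis is orthogonalized against the plane
#' normal, so the resulting rotation is exactly orthonormal. Recipes are data,
#' not code: swap in laboratory-specific definitions freely.
#'
#' @return Named list of recipes, one per segment, each a list with entries
#'   `origin`, `axis_from`, `axis_to` (marker names or pairs to midpoint) and
#'   `plane` (three marker names).
#' @export
default_recipes <- function() {
  list(
    shank = list(origin = c("MC", "LC"), axis_from = c("SH3", "SH4"),
                 axis_to = c("SH1", "SH2"), plane = c("SH1", "SH2", "SH3"),
                 long_axis = "vertical"),
    hindfoot = list(origin = "C1", axis_from = "C1", axis_to = "H2",
                    plane = c("C1", "MC", "LC")),
    forefoot = list(origin = c("B1", "B5"), axis_from = c("B1", "B5"),
                    axis_to = c("H1", "H3"), plane = c("B1", "B5", "H2")),
    hallux = list(origin = c("H1", "H3"), axis_from = c("H1", "H3"),
                  axis_to = "HX", plane = c("H1", "H3", "HX"))
  )
}

#' Default joint-center marker pairs
#'
#' Joint centers are midpoints of a medial/lateral marker pair, the convention
#' of multisegment kinetic foot models: ankle between MC and LC, midtarsal
#' between navicular and cuboid, metatarsophalangeal between the first and
#' third metatarsal head markers.
#'
#' @return Named list of character pairs.
#' @export
default_joint_pairs <- function() {
  list(ankle = c("MC", "LC"), mt = c("NV", "CU"), mp = c("H1", "H3"))
}

resolve_point <- function(ms, spec, frame) {
  if (length(spec) == 1L) return(marker_xyz(ms, spec, frame))
  (marker_xyz(ms, spec[1L], frame) + marker_xyz(ms, spec[2L], frame)) / 2
}

#' Build one segment coordinate frame sample from markers
#'
#' The plane markers define an approximate superior normal; the long axis is
#' projected into the plane orthogonal to it (Gram-Schmidt), giving a
#' right-handed orthonormal rotation with columns (x lateral, y anterior,
#' z up) expressed in the global frame. For the shank (recipe flag
#' `long_axis = "vertical"`) the dominant axis is the vertical one and the
#' plane sets the anterior direction instead.
#'
#' @param markers a [marker_set()].
#' @param recipe one entry of [default_recipes()].
#' @param frame_index frame number.
#' @return List with `origin` (3-vector, m) and `rotation` (3x3, local to
#'   global).
#' @export
build_segment_frame <- function(markers, recipe, frame_index) {
  O <- resolve_point(markers, recipe$origin, frame_index)
  a <- resolve_point(markers, recipe$axis_to, frame_index) -
       resolve_point(markers, recipe$axis_from, frame_index)
  p1 <- marker_xyz(markers, recipe$plane[1L], frame_index)
  p2 <- marker_xyz(markers, recipe$plane[2L], frame_index)
  p3 <- marker_xyz(markers, recipe$plane[3L], frame_index)
  if (anyNA(c(O, a, p1, p2, p3)))
    abort("missing marker sample in frame recipe", "missing_marker_error")
  n <- cross3(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-12)
    abort("plane markers are collinear or coincident", "degenerate_error")
  if (sqrt(sum(a^2)) < 1e-12)
    abort("long-axis markers coincide", "degenerate_error")
  n <- unit(n)
  if (identical(recipe$long_axis, "vertical")) {
    # shank: the long axis points up the segment; the cluster-plane normal
    # (marker order chosen so it faces anterior) sets the forward direction
    z <- unit(a)
    y <- n - sum(n * z) * z
    if (sqrt(sum(y^2)) < 1e-12) abort("degenerate shank recipe", "degenerate_error")
    y <- unit(y)
    x <- cross3(y, z)
  } else {
    if (n[3L] < 0) n <- -n                     # superior normal
    y <- a - sum(a * n) * n
    if (sqrt(sum(y^2)) < 1e-12)
      abort("long axis is parallel to the plane normal", "degenerate_error")
    y <- unit(y)
    z <- n
    x <- cross3(y, z)
  }
  R <- cbind(x, y, z, deparse.level = 0)
  dimnames(R) <- NULL
  list(origin = unname(O), rotation = R)
}

#' Segment frames for every frame of a trial
#'
#' @param markers a [marker_set()].
#' @param recipe one entry of [default_recipes()].
#' @return List with `origin` (`frames x 3`) and `rotation`
#'   (`3 x 3 x frames`).
#' @export
segment_frames <- function(markers, recipe) {
  nf <- markers$frames
  origin <- matrix(NA_real_, nf, 3L)
  rotation <- array(NA_real_, c(3L, 3L, nf))
  for (i in seq_len(nf)) {
    s <- build_segment_frame(markers, recipe, i)
    origin[i, ] <- s$origin
    rotation[, , i] <- s$rotation
  }
  list(origin = origin, rotation = rotation)
}

#' Joint-center trajectory as a marker-pair midpoint
#'
#' @param markers a [marker_set()].
#' @param joint `"ankle"`, `"mt"` or `"mp"`.
#' @param pair character vector of the two marker names (defaults from
#'   [default_joint_pairs()]).
#' @return Object of class `joint_center_track`: `joint`, `position`
#'   (`frames x 3`, m, global), `recipe`.
#' @export
joint_center <- function(markers, joint = c("ankle", "mt", "mp"), pair = NULL) {
  joint <- match.arg(joint)
  if (is.null(pair)) pair <- default_joint_pairs()[[joint]]
  for (m in pair)
    if (!m %in% markers$names)
      abort(sprintf("joint_center(%s): marker '%s' not present", joint, m),
            "missing_marker_error")
  p1 <- markers$positions[[pair[1L]]]
  p2 <- markers$positions[[pair[2L]]]
  if (all(abs(p1 - p2) < 1e-12, na.rm = TRUE))
    warnf("joint_center(%s): markers %s and %s coincide", joint, pair[1L], pair[2L])
  structure(list(joint = joint, position = (p1 + p2) / 2, recipe = pair),
            class = "joint_center_track")
}

#' Compose a rotation from Cardan angles
#'
#' Order: flexion about x, then abduction about z, then inversion about y
#' (`R = Rx(a) %*% Rz(b) %*% Ry(c)`).
#'
#' @param angles numeric 3-vector `(dfpf, abad, inev)` in degrees.
#' @return 3x3 rotation matrix.
#' @export
compose_cardan <- function(angles) {
  r <- angles * pi / 180
  ca <- cos(r[1L]); sa <- sin(r[1L])
  cb <- cos(r[2L]); sb <- sin(r[2L])
  cg <- cos(r[3L]); sg <- sin(r[3L])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
  Rz <- matrix(c(cb, sb, 0, -sb, cb, 0, 0, 0, 1), 3L, 3L)
  Ry <- matrix(c(cg, 0, -sg, 0, 1, 0, sg, 0, cg), 3L, 3L)
  Rx %*% Rz %*% Ry
}

#' Decompose a relative rotation into Cardan angles
#'
#' Inverse of [compose_cardan()]. Near gimbal lock (second angle within about
#' 1e-6 degrees of +/-90) the third angle is conventionally set to 0 and the
#' result is flagged.
#'
#' @param R_rel 3x3 relative rotation (distal in proximal), orthonormal.
#' @return Named numeric 3-vector `(dfpf, abad, inev)` in degrees, with
#'   attribute `gimbal_lock` (logical).
#' @export
cardan_angles <- function(R_rel) {
  err <- max(abs(crossprod(R_rel) - diag(3)))
  if (err > 1e-6) abort("R_rel is not orthonormal", "validation_error")
  sb <- -R_rel[1L, 2L]
  sb <- min(1, max(-1, sb))
  beta <- asin(sb)
  lock <- abs(abs(beta) - pi / 2) < 1e-6 * pi / 180 || abs(cos(beta)) < 1e-9
  if (lock) {
    # third rotation unidentifiable: fold it into the first, report gamma = 0
    alpha <- atan2(R_rel[3L, 1L] * sign(sb), R_rel[2L, 1L] * sign(sb))
    gamma <- 0
  } else {
    alpha <- atan2(R_rel[3L, 2L], R_rel[2L, 2L])
    gamma <- atan2(R_rel[1L, 3L], R_rel[1L, 1L])
  }
  out <- c(dfpf = alpha, abad = beta, inev = gamma) * 180 / pi
  attr(out, "gimbal_lock") <- lock
  out
}

#' Cardan joint angles of a trial relative to the static reference
#'
#' For each joint the distal-in-proximal rotation is formed per frame and
#' referenced to the static posture by premultiplying with the inverse of the
#' static relative rotation, so all angles are exactly zero in the reference
#' posture.
#'
#' @param markers dynamic [marker_set()] (filter first if desired).
#' @param static_markers static-reference [marker_set()].
#' @param recipes segment recipes, see [default_recipes()].
#' @return Named list (ankle, mt, mp) of `frames x 3` matrices (degrees),
#'   columns `dfpf, abad, inev`.
#' @export
joint_angles <- function(markers, static_markers, recipes = default_recipes()) {
  pairs <- list(ankle = c("shank", "hindfoot"),
                mt = c("hindfoot", "forefoot"),
                mp = c("forefoot", "hallux"))
  segs <- unique(unlist(pairs))
  dyn <- lapply(recipes[segs], segment_frames, markers = markers)
  sta <- lapply(recipes[segs], build_segment_frame, markers = static_markers,
                frame_index = 1L)
  out <- list()
  for (j in names(pairs)) {
    prox <- pairs[[j]][1L]; dist <- pairs[[j]][2L]
    R_ref <- t(sta[[prox]]$rotation) %*% sta[[dist]]$rotation
    nf <- markers$frames
    ang <- matrix(NA_real_, nf, 3L, dimnames = list(NULL, c("dfpf", "abad", "inev")))
    for (i in seq_len(nf)) {
      R_rel <- t(dyn[[prox]]$rotation[, , i]) %*% dyn[[dist]]$rotation[, , i]
      ang[i, ] <- cardan_angles(t(R_ref) %*% R_rel)
    }
    out[[j]] <- ang
  }
  out
}

#' Foot progression angle from the heel and forefoot markers
#'
#' Signed angle between the ground-plane projection of the C1 -> H2 line and
#' the global anterior (+Y) axis; toe-out towards +X is positive. Result in
#' (-pi, pi], radians.
#'
#' @param c1,h2 3D (or 2D) points, m.
#' @return Angle in radians.
#' @export
foot_angle <- function(c1, h2) {
  d <- unname(h2[1:2] - c1[1:2])
  if (sqrt(sum(d^2)) < 1e-12)
    abort("C1 and H2 coincide in the ground plane", "degenerate_error")
  atan2(d[1L], d[2L])
}
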