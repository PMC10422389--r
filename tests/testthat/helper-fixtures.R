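# Shared fixtures, built in code.

# small grid with unit-cm cells centered so cell (1,1) is at the origin
tiny_geometry <- function(n_rows = 4L, n_cols = 3L, pitch = 0.01,
                          origin = c(0, 0), orientation = 0,
                          frame = "global") {
  grid_geometry(n_rows, n_cols, pitch, pitch, origin, orientation, frame)
}

# a marker set with constant positions from a named list of 3-vectors
static_marker_set <- function(points, frames = 5L, rate = 100) {
  marker_set(lapply(points, function(p) matrix(rep(p, each = frames), frames, 3L)),
             rate)
}

# random orthonormal rotation via QR, det +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# point-in-convex-hull test for 2D (used for CoP containment)
in_convex_hull <- function(pt, pts, tol = 1e-9) {
  if (nrow(pts) == 1L) return(sqrt(sum((pt - pts[1L, ])^2)) < tol)
  if (nrow(pts) == 2L) {
    d <- pts[2L, ] - pts[1L, ]
    t <- sum((pt - pts[1L, ]) * d) / sum(d^2)
    return(t > -tol && t < 1 + tol &&
             abs((pt[1L] - pts[1L, 1L]) * d[2L] - (pt[2L] - pts[1L, 2L]) * d[1L]) < tol)
  }
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  n <- nrow(poly)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (b[1L] - a[1L]) * (pt[2L] - a[2L]) - (b[2L] - a[2L]) * (pt[1L] - a[1L])
    if (abs(cr) < tol) next
    if (sgn == 0) sgn <- sign(cr) else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

fast_model <- function(...) gait_model(stance_duration = 0.6, ...)

quiet_fit <- function(trial, device, config = pipeline_config()) {
  suppressWarnings(foot_kinetics(trial, device, config))
}
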