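# Internal helpers: classed conditions and small numerics shared across modules.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("footkinetics_", class), "footkinetics_error"),
                      call = call))
}

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a (near-)zero vector", "degenerate_error")
  v / n
}

# 2D rotation matrix, counter-clockwise about +Z viewed from above
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# rotation taking +Y toward +X by theta: the foot-progression-angle sign
# convention (positive = toe-out to +X), i.e. rot2(-theta)
rot2cw <- function(theta) rot2(-theta)

# rotation about global Z as a 3x3 matrix
rotz3 <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3L, 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
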