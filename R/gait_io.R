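# Core record types and file I/O.
#
# Unit policy, enforced by every reader: meters, seconds, newtons, N.m,
# kilopascals (pressure), kilograms. Marker files in millimetres are converted
# on read.

MARKER_NAMES <- c("C1", "C2", "MC", "LC", "B1", "H2", "HX", "H1", "H3",
                  "NV", "CU", "B5")
SHANK_MARKERS <- c("SH1", "SH2", "SH3", "SH4")

#' Construct a set of named 3D marker trajectories
#'
#' Holds synchronized marker trajectories in the laboratory (global) frame.
#' Missing samples are represented as `NA` rows and are never silently
#' interpolated; see [fill_gaps()].
#'
#' @param positions named list of `frames x 3` numeric matrices (meters,
#'   global frame), one per marker.
#' @param rate sampling frequency in Hz.
#' @return An object of class `marker_set` with fields `names`, `positions`,
#'   `rate` and `frames`.
#' @export
marker_set <- function(positions, rate) {
  if (!is.list(positions) || is.null(names(positions)) || any(names(positions) == ""))
    abort("positions must be a named list of frames x 3 matrices", "validation_error")
  if (anyDuplicated(names(positions)))
    abort(sprintf("duplicate marker labels: %s",
                  paste(unique(names(positions)[duplicated(names(positions))]), collapse = ", ")),
          "validation_error")
  if (!is_scalar_num(rate) || rate <= 0)
    abort("rate must be a positive number (Hz)", "validation_error")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) abort("each marker trajectory must have 3 columns", "validation_error")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y", "z")
    p
  })
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    abort("all markers must share the same frame count", "validation_error")
  structure(list(names = names(positions), positions = positions,
                 rate = rate, frames = nf[[1L]]),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers, %d frames @ %g Hz\n",
              length(x$names), x$frames, x$rate))
  cat("  markers:", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

marker_xyz <- function(ms, name, frame = NULL) {
  if (!name %in% ms$names)
    abort(sprintf("marker '%s' not present", name), "missing_marker_error")
  p <- ms$positions[[name]]
  if (is.null(frame)) p else p[frame, ]
}

#' Fill short gaps in marker trajectories by linear interpolation
#'
#' Gap filling is opt-in: readers flag missing samples as `NA` and leave them.
#'
#' @param ms a [marker_set()].
#' @param max_gap longest run of consecutive missing frames to fill (default 10).
#' @return A `marker_set` with fillable gaps interpolated; leading/trailing
#'   gaps and runs longer than `max_gap` are left missing.
#' @export
fill_gaps <- function(ms, max_gap = 10L) {
  pos <- lapply(ms$positions, function(p) {
    miss <- rowSums(is.na(p)) > 0L
    if (!any(miss)) return(p)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] > max_gap) next
      if (starts[k] == 1L || ends[k] == nrow(p)) next   # cannot extrapolate
      i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
      w <- (starts[k]:ends[k] - i0) / (i1 - i0)
      for (j in 1:3) p[starts[k]:ends[k], j] <- p[i0, j] + w * (p[i1, j] - p[i0, j])
    }
    p
  })
  marker_set(pos, ms$rate)
}

#' Read marker trajectories from disk
#'
#' Supported formats: long CSV (columns `frame, marker, x, y, z`, optional
#' leading comment `# rate_hz: <Hz>`) and TRC. Coordinates are converted to
#' meters (`mm` inputs divided by 1000). C3D is not supported natively:
#' convert to TRC or CSV first.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"trc"`, `"c3d"`.
#' @param units coordinate units of a CSV file, `"m"` or `"mm"`; TRC declares
#'   its units in the header.
#' @param rate sampling rate override (Hz) for CSV files without a rate comment.
#' @return A [marker_set()].
#' @export
read_markers <- function(path, format = c("csv", "trc", "c3d"), units = "m",
                         rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "io_error")
  switch(format,
    csv = read_markers_csv(path, units = units, rate = rate),
    trc = read_markers_trc(path),
    c3d = abort("C3D input is not supported by this build; convert to TRC or long CSV",
                "format_error"))
}

read_markers_csv <- function(path, units = "m", rate = NULL) {
  if (!units %in% c("m", "mm")) abort("units must be 'm' or 'mm'", "format_error")
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*rate_hz:", first))
    rate <- as.numeric(sub("^#\\s*rate_hz:\\s*", "", first))
  if (is.null(rate)) abort("sampling rate unknown: no '# rate_hz:' header and no rate argument",
                           "format_error")
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(d)))
    abort("marker CSV must have columns frame, marker, x, y, z", "format_error")
  # duplicate labels manifest as duplicated (frame, marker) pairs
  if (anyDuplicated(d[, c("frame", "marker")]))
    abort("duplicate marker label / frame combination in CSV", "validation_error")
  scale <- if (units == "mm") 1e-3 else 1
  markers <- unique(d$marker)
  frames <- sort(unique(d$frame))
  nf <- length(frames)
  pos <- lapply(markers, function(m) {
    sub <- d[d$marker == m, ]
    p <- matrix(NA_real_, nf, 3L)
    idx <- match(sub$frame, frames)
    p[idx, ] <- as.matrix(sub[, c("x", "y", "z")]) * scale
    p
  })
  names(pos) <- markers
  marker_set(pos, rate)
}

read_markers_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) abort("TRC file too short", "format_error")
  hdr_keys <- strsplit(lines[2L], "\t")[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t")[[1L]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_keys)
  rate <- as.numeric(hdr[["DataRate"]])
  units <- hdr[["Units"]] %||% "mm"
  scale <- if (identical(units, "mm")) 1e-3 else 1
  labels <- strsplit(lines[4L], "\t")[[1L]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  if (anyDuplicated(labels))
    abort("duplicate marker labels in TRC header", "validation_error")
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- lapply(strsplit(data_lines, "\t"), function(v) suppressWarnings(as.numeric(v)))
  nf <- length(vals)
  nm <- length(labels)
  pos <- lapply(seq_len(nm), function(j) {
    p <- t(vapply(vals, function(v) v[2L + (j - 1L) * 3L + 1:3], numeric(3))) * scale
    p
  })
  names(pos) <- labels
  marker_set(pos, rate)
}

#' Write marker trajectories as long CSV
#'
#' @param ms a [marker_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", ms$rate), con)
  rows <- do.call(rbind, lapply(ms$names, function(m) {
    p <- ms$positions[[m]]
    data.frame(frame = seq_len(nrow(p)), marker = m,
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  utils::write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Describe the geometry of a pressure-sensing grid
#'
#' Cell `(i, j)` (row `i`, column `j`, 1-based) has in-grid coordinates
#' `((j-1) * pitch_x, (i-1) * pitch_y)`; rows advance along the grid's
#' anterior axis. `origin` and `orientation` place the grid in its frame of
#' reference (`"global"` for the platform; `"foot"` for the insole, which
#' travels with the foot and needs registration).
#'
#' @param n_rows,n_cols cell counts.
#' @param pitch_x,pitch_y cell spacing (m).
#' @param origin 2D coordinate of the center of cell (1,1) (m).
#' @param orientation rotation of grid axes relative to frame axes (rad),
#'   in (-pi, pi].
#' @param frame_of_reference `"global"` or `"foot"`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, pitch_x, pitch_y,
                          origin = c(0, 0), orientation = 0,
                          frame_of_reference = c("global", "foot")) {
  frame_of_reference <- match.arg(frame_of_reference)
  if (pitch_x <= 0 || pitch_y <= 0) abort("pitches must be positive", "validation_error")
  if (orientation <= -pi || orientation > pi)
    abort("orientation must lie in (-pi, pi]", "validation_error")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_x = pitch_x, pitch_y = pitch_y,
                 origin = as.numeric(origin), orientation = orientation,
                 frame_of_reference = frame_of_reference),
            class = "grid_geometry")
}

#' Cell-center coordinates of a grid
#'
#' @param geometry a [grid_geometry()].
#' @return A `(n_rows * n_cols) x 2` matrix of cell centers in the grid's
#'   frame of reference, in column-major cell order (matching `as.vector` of a
#'   pressure matrix).
#' @export
cell_centers <- function(geometry) {
  i <- rep(seq_len(geometry$n_rows), times = geometry$n_cols)
  j <- rep(seq_len(geometry$n_cols), each = geometry$n_rows)
  local <- cbind((j - 1) * geometry$pitch_x, (i - 1) * geometry$pitch_y)
  pts <- local %*% t(rot2(geometry$orientation))
  sweep(pts, 2L, geometry$origin, "+")
}

#' Construct a pressure-grid time series
#'
#' Values above `p_max` are clipped to `p_max` and flagged in
#' `saturated_mask`; values below the sensing floor `p_min` are stored as 0.
#'
#' @param frames `n_rows x n_cols x n_frames` array of pressures (kPa), or a
#'   list of matrices.
#' @param geometry a [grid_geometry()].
#' @param rate sampling frequency (Hz).
#' @param device `"platform"` or `"insole"`.
#' @param p_min,p_max sensing range (kPa); defaults are the platform's
#'   4--1000 kPa and the insole's 4--862 kPa.
#' @return An object of class `pressure_sequence`.
#' @export
pressure_sequence <- function(frames, geometry, rate,
                              device = c("platform", "insole"),
                              p_min = NULL, p_max = NULL) {
  device <- match.arg(device)
  if (is.null(p_min)) p_min <- 4
  if (is.null(p_max)) p_max <- if (device == "platform") 1000 else 862
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  if (dim(frames)[1L] != geometry$n_rows || dim(frames)[2L] != geometry$n_cols)
    abort("pressure matrix shape does not match grid geometry", "validation_error")
  if (anyNA(frames)) abort("pressure frames must be finite", "validation_error")
  if (min(frames) < 0) abort("negative pressures are not physical", "validation_error")
  saturated <- frames > p_max
  frames[saturated] <- p_max
  frames[frames < p_min] <- 0      # below sensing floor
  structure(list(frames = frames, geometry = geometry, rate = rate,
                 device = device, p_min = p_min, p_max = p_max,
                 saturated_mask = saturated,
                 n_frames = dim(frames)[3L]),
            class = "pressure_sequence")
}

#' @export
print.pressure_sequence <- function(x, ...) {
  cat(sprintf("<pressure_sequence> %s, %dx%d cells, %d frames @ %g Hz, range %g-%g kPa\n",
              x$device, x$geometry$n_rows, x$geometry$n_cols, x$n_frames,
              x$rate, x$p_min, x$p_max))
  invisible(x)
}

#' Read a pressure sequence from a long CSV plus JSON geometry sidecar
#'
#' The CSV stores only non-zero cells (`frame, row, col, pressure_kpa`); the
#' sidecar stores grid geometry, device, rate and sensing range.
#'
#' @param path CSV file of cell pressures.
#' @param geometry_meta JSON sidecar path.
#' @return A [pressure_sequence()].
#' @export
read_pressure <- function(path, geometry_meta) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "io_error")
  meta <- jsonlite::read_json(geometry_meta, simplifyVector = TRUE)
  geom <- grid_geometry(meta$n_rows, meta$n_cols, meta$pitch_x, meta$pitch_y,
                        meta$origin, meta$orientation, meta$frame_of_reference)
  d <- utils::read.csv(path)
  need <- c("frame", "row", "col", "pressure_kpa")
  if (!all(need %in% names(d)))
    abort("pressure CSV must have columns frame, row, col, pressure_kpa", "format_error")
  if (any(d$row > geom$n_rows | d$col > geom$n_cols | d$row < 1 | d$col < 1))
    abort("cell indices outside grid geometry", "validation_error")
  if (any(d$pressure_kpa < 0)) abort("negative pressures are not physical", "validation_error")
  nf <- meta$n_frames %||% max(d$frame, 1L)
  arr <- array(0, c(geom$n_rows, geom$n_cols, nf))
  arr[cbind(d$row, d$col, d$frame)] <- d$pressure_kpa
  pressure_sequence(arr, geom, rate = meta$rate_hz, device = meta$device,
                    p_min = meta$p_min, p_max = meta$p_max)
}

#' Write a pressure sequence (sparse CSV + JSON geometry sidecar)
#'
#' @param seq a [pressure_sequence()].
#' @param path output CSV path.
#' @param geometry_meta output JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_pressure <- function(seq, path, geometry_meta) {
  idx <- which(seq$frames > 0, arr.ind = TRUE)
  d <- data.frame(frame = idx[, 3L], row = idx[, 1L], col = idx[, 2L],
                  pressure_kpa = seq$frames[idx])
  d <- d[order(d$frame, d$row, d$col), ]
  utils::write.csv(d, path, row.names = FALSE)
  g <- seq$geometry
  meta <- list(n_rows = g$n_rows, n_cols = g$n_cols, pitch_x = g$pitch_x,
               pitch_y = g$pitch_y, origin = g$origin, orientation = g$orientation,
               frame_of_reference = g$frame_of_reference, device = seq$device,
               rate_hz = seq$rate, p_min = seq$p_min, p_max = seq$p_max,
               n_frames = seq$n_frames)
  jsonlite::write_json(meta, geometry_meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trial metadata
#'
#' @param subject_id subject label.
#' @param body_mass body mass in kg (> 0).
#' @param shoe shoe condition, `"A"` or `"B"`.
#' @param device primary analysis device, `"platform"` or `"insole"`.
#' @param trial_index repetition index (>= 1).
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, body_mass, shoe = c("A", "B"),
                       device = c("platform", "insole"), trial_index = 1L) {
  shoe <- match.arg(shoe); device <- match.arg(device)
  if (!is_scalar_num(body_mass) || body_mass <= 0)
    abort("body_mass must be positive (kg)", "validation_error")
  if (trial_index < 1) abort("trial_index must be >= 1", "validation_error")
  structure(list(subject_id = as.character(subject_id), body_mass = body_mass,
                 shoe = shoe, device = device, trial_index = as.integer(trial_index)),
            class = "trial_meta")
}

#' Assemble a gait trial
#'
#' All streams are assumed hardware-synchronized at a common rate and time
#' origin; an integer frame offset per stream can be applied upstream.
#'
#' @param meta a [trial_meta()].
#' @param markers dynamic [marker_set()].
#' @param platform platform [pressure_sequence()] (global frame).
#' @param insole insole [pressure_sequence()] (foot frame).
#' @param static_reference standing static [marker_set()].
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(meta, markers, platform, insole, static_reference) {
  rates <- c(markers$rate, platform$rate, insole$rate)
  if (max(rates) - min(rates) > 1e-9)
    abort("all streams must share one sampling rate", "validation_error")
  if (platform$geometry$frame_of_reference != "global")
    abort("platform grid must be fixed in the global frame", "validation_error")
  if (insole$geometry$frame_of_reference != "foot")
    abort("insole grid must be fixed in the foot frame", "validation_error")
  structure(list(meta = meta, markers = markers, platform = platform,
                 insole = insole, static_reference = static_reference),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s, shoe %s, trial %d, mass %.1f kg\n",
              x$meta$subject_id, x$meta$shoe, x$meta$trial_index, x$meta$body_mass))
  cat(sprintf("  markers: %d @ %g Hz, %d frames; platform %dx%d; insole %dx%d\n",
              length(x$markers$names), x$markers$rate, x$markers$frames,
              x$platform$geometry$n_rows, x$platform$geometry$n_cols,
              x$insole$geometry$n_rows, x$insole$geometry$n_cols))
  invisible(x)
}

#' Write a trial to a directory of plain-text files
#'
#' @param trial a [gait_trial()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(trial$meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_markers(trial$markers, file.path(dir, "markers.csv"))
  write_markers(trial$static_reference, file.path(dir, "static.csv"))
  write_pressure(trial$platform, file.path(dir, "platform.csv"),
                 file.path(dir, "platform_geometry.json"))
  write_pressure(trial$insole, file.path(dir, "insole.csv"),
                 file.path(dir, "insole_geometry.json"))
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir trial directory.
#' @return A [gait_trial()].
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  gait_trial(
    trial_meta(meta$subject_id, meta$body_mass, meta$shoe, meta$device, meta$trial_index),
    read_markers(file.path(dir, "markers.csv"), "csv"),
    read_pressure(file.path(dir, "platform.csv"), file.path(dir, "platform_geometry.json")),
    read_pressure(file.path(dir, "insole.csv"), file.path(dir, "insole_geometry.json")),
    read_markers(file.path(dir, "static.csv"), "csv"))
}

#' Write result curves and the long-format parameter table
#'
#' Curves are written as a wide CSV with 101 rows (0..100% stance): a `pct`
#' column plus one column per curve component, named
#' `<id>.<joint>.<motion>`. Parameters go to a long CSV with columns
#' `subject, shoe, device, trial, joint, motion, parameter, value`.
#'
#' @param curves named list of `moment_curve` objects (names become curve ids).
#' @param params long-format parameter data frame (may be empty).
#' @param path output directory.
#' @return Named character vector of the files written (the manifest).
#' @export
write_results <- function(curves, params, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create output directory %s", path), "io_error")
  manifest <- character(0)
  if (length(curves)) {
    if (is.null(names(curves)) || any(names(curves) == ""))
      names(curves) <- sprintf("curve%02d", seq_along(curves))
    wide <- data.frame(pct = 0:100)
    for (id in names(curves)) {
      cv <- curves[[id]]
      stopifnot(inherits(cv, "moment_curve"))
      for (m in colnames(cv$values))
        wide[[paste(id, cv$joint, m, sep = ".")]] <- cv$values[, m]
    }
    f <- file.path(path, "curves.csv")
    utils::write.csv(wide, f, row.names = FALSE)
    manifest <- c(manifest, curves = f)
  }
  cols <- c("subject", "shoe", "device", "trial", "joint", "motion", "parameter", "value")
  if (is.null(params) || nrow(params) == 0L) {
    warnf("parameter table is empty; writing header-only CSV")
    params <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  if (!all(cols %in% names(params)))
    abort("parameter table must have the long-format columns", "validation_error")
  f <- file.path(path, "parameters.csv")
  utils::write.csv(params[, cols], f, row.names = FALSE)
  manifest <- c(manifest, parameters = f)
  manifest
}
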