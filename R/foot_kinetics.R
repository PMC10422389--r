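#' Fit the multisegment foot kinetics pipeline to one gait trial
#'
#' The front end of the package: takes a synchronized trial (markers +
#' platform + insole pressures) and one analysis device, and returns the
#' segmented contact-force and 3D joint-moment curves at the ankle, midtarsal
#' and metatarsophalangeal joints, time-normalized to 0..100% stance and
#' body-weight normalized, together with their peak descriptors
#' (MaxVal/TMax, MinVal/TMin).
#'
#' @param trial a [gait_trial()].
#' @param device analysis device, `"platform"` or `"insole"`.
#' @param config a [pipeline_config()].
#' @return An object of class `foot_kinetics` with components
#'   \describe{
#'     \item{moments}{named list (ankle, mt, mp) of `moment_curve` objects,
#'       each `values` a 101 x 3 matrix (dfpf, abad, inev), N.m/kg.}
#'     \item{forces}{named list of 101-sample segmented normal-force curves (N).}
#'     \item{params}{long-format data frame of peak descriptors.}
#'     \item{stance}{onset/offset frames and duration (s).}
#'     \item{transform}{insole-to-global [rigid_transform2d()] (insole device).}
#'     \item{meta, device, config}{provenance.}
#'   }
#' @seealso [moment_curves()] for the underlying computation,
#'   [simulate_trial()] for synthetic input.
#' @examples
#' model <- gait_model(seed = 1)
#' trial <- simulate_trial(model)$trial
#' fit <- foot_kinetics(trial, "platform")
#' fit
#' head(coef(fit))
#' @export
foot_kinetics <- function(trial, device = c("platform", "insole"),
                          config = pipeline_config()) {
  device <- match.arg(device)
  stopifnot(inherits(trial, "gait_trial"))
  cs <- moment_curves(trial, device, config)
  params <- curve_param_rows(cs)
  structure(list(moments = cs$moments, forces = cs$forces, params = params,
                 stance = list(onset = cs$stance[[1L]], offset = cs$stance[[2L]],
                               duration = (cs$stance[[2L]] - cs$stance[[1L]]) /
                                 trial$markers$rate),
                 transform = cs$transform, meta = trial$meta, device = device,
                 config = config),
            class = "foot_kinetics")
}

curve_param_rows <- function(cs) {
  rows <- list()
  for (j in names(cs$moments)) {
    for (m in colnames(cs$moments[[j]]$values)) {
      p <- extract_params(cs$moments[[j]]$values[, m])
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, motion = m,
        parameter = c("MaxVal", "TMax", "MinVal", "TMin"),
        value = c(p$max_val, p$t_max, p$min_val, p$t_min))
    }
    p <- extract_params(cs$forces[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      joint = j, motion = "force",
      parameter = c("MaxVal", "TMax"), value = c(p$max_val, p$t_max))
  }
  do.call(rbind, rows)
}

#' @export
print.foot_kinetics <- function(x, ...) {
  cat(sprintf("Multisegment foot kinetics fit (%s device)\n", x$device))
  cat(sprintf("  subject %s, shoe %s, trial %d, body mass %.1f kg\n",
              x$meta$subject_id, x$meta$shoe, x$meta$trial_index, x$meta$body_mass))
  cat(sprintf("  stance: frames %d-%d (%.2f s)\n",
              x$stance$onset, x$stance$offset, x$stance$duration))
  pk <- x$params[x$params$motion == "dfpf" & x$params$parameter == "MaxVal", ]
  cat("  peak DF/PF moments (N.m/kg): ",
      paste(sprintf("%s %.3f", pk$joint, pk$value), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.foot_kinetics <- function(object, ...) {
  structure(list(meta = object$meta, device = object$device,
                 stance = object$stance, params = object$params),
            class = "summary.foot_kinetics")
}

#' @export
print.summary.foot_kinetics <- function(x, ...) {
  cat(sprintf("Foot kinetics summary - subject %s, shoe %s, trial %d, %s device\n",
              x$meta$subject_id, x$meta$shoe, x$meta$trial_index, x$device))
  cat(sprintf("Stance %.2f s (frames %d-%d)\n\n", x$stance$duration,
              x$stance$onset, x$stance$offset))
  wide <- stats::reshape(x$params, idvar = c("joint", "motion"),
                         timevar = "parameter", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Peak descriptors of a fitted trial
#'
#' @param object a `foot_kinetics` fit.
#' @param ... unused.
#' @return Long-format data frame: `joint, motion, parameter, value`
#'   (moment parameters in N.m/kg or % stance; force rows in N).
#' @export
coef.foot_kinetics <- function(object, ...) object$params

#' Plot the moment (and force) curves of a fitted trial
#'
#' One panel per joint: the three moment components against % stance, or the
#' segmented normal-force curves with `what = "forces"`.
#'
#' @param x a `foot_kinetics` fit.
#' @param what `"moments"` or `"forces"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.foot_kinetics <- function(x, what = c("moments", "forces"), ...) {
  what <- match.arg(what)
  pct <- 0:100
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(ankle = "Ankle", mt = "Midtarsal", mp = "Metatarsophalangeal")
  for (j in names(labs)) {
    if (what == "moments") {
      graphics::matplot(pct, x$moments[[j]]$values, type = "l", lty = 1,
                        col = c("black", "grey55", "firebrick"),
                        xlab = "% stance", ylab = "moment (N.m/kg)",
                        main = labs[[j]], ...)
      graphics::abline(h = 0, col = "grey80")
      graphics::legend("topleft", bty = "n", lty = 1,
                       col = c("black", "grey55", "firebrick"),
                       legend = c("DF/PF", "AB/AD", "IN/EV"), cex = 0.8)
    } else {
      graphics::plot(pct, x$forces[[j]], type = "l", xlab = "% stance",
                     ylab = "segmented force (N)", main = labs[[j]], ...)
    }
  }
  invisible(x)
}

#' Plot mean and confidence ribbon of a set of curves
#'
#' Reproduces the standard presentation of gait curves: per-subject means,
#' grand mean and pointwise t-based confidence band versus % stance.
#'
#' @param curves `n_subjects x 101` matrix of per-subject mean curves.
#' @param level confidence level (default 0.95).
#' @param ylab,main plot annotation.
#' @param col ribbon color.
#' @return The [mean_ci_curves()] result, invisibly.
#' @export
plot_mean_ci <- function(curves, level = 0.95, ylab = "moment (N.m/kg)",
                         main = "", col = grDevices::adjustcolor("steelblue", 0.35)) {
  ci <- mean_ci_curves(curves, level)
  pct <- seq(0, 100, length.out = length(ci$mean))
  graphics::plot(pct, ci$mean, type = "n", ylim = range(ci$lower, ci$upper),
                 xlab = "% stance", ylab = ylab, main = main)
  graphics::polygon(c(pct, rev(pct)), c(ci$lower, rev(ci$upper)),
                    col = col, border = NA)
  graphics::lines(pct, ci$mean, lwd = 2)
  invisible(ci)
}
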