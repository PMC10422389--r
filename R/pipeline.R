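# Pipeline orchestration: configuration, the full study design in silico,
# batch processing and the device-agreement report.

#' Pipeline configuration
#'
#' Defaults reproduce the published acquisition settings where stated
#' (10 Hz kinematic and 50 Hz kinetic fourth-order zero-phase Butterworth
#' cutoffs, registration 0.1 s after initial contact, 101-point stance grid);
#' the remaining values (stance threshold, segmentation axis, tie-breaks) are
#' this package's documented design choices.
#'
#' @param kinematic_cutoff marker low-pass cutoff (Hz).
#' @param kinetic_cutoff kinetic low-pass cutoff (Hz); cutoffs at/above
#'   Nyquist are clipped to 0.95 x Nyquist with a warning.
#' @param stance_threshold force threshold (N) for stance detection, or
#'   `NULL` for `max(10, 1.5% body weight)`.
#' @param min_stance_frames minimum frames above threshold.
#' @param min_stance_duration shortest valid stance (s); shorter trials are
#'   rejected.
#' @param registration_delay CoP-matching delay after initial contact (s).
#' @param resample_n stations of the percent-stance grid.
#' @param ci_level confidence level for mean curves.
#' @param segmentation_axis `"foot"` (C1->H2 direction) or `"global"` (+Y).
#' @param gap_fill,max_gap marker gap-filling policy.
#' @param recipes segment-frame recipes ([default_recipes()]).
#' @param joint_pairs joint-center marker pairs ([default_joint_pairs()]).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(kinematic_cutoff = 10,
                            kinetic_cutoff = 50,
                            stance_threshold = NULL,
                            min_stance_frames = 3L,
                            min_stance_duration = 0.2,
                            registration_delay = 0.1,
                            resample_n = 101L,
                            ci_level = 0.95,
                            segmentation_axis = c("foot", "global"),
                            gap_fill = FALSE,
                            max_gap = 10L,
                            recipes = default_recipes(),
                            joint_pairs = default_joint_pairs()) {
  structure(list(kinematic_cutoff = kinematic_cutoff,
                 kinetic_cutoff = kinetic_cutoff,
                 stance_threshold = stance_threshold,
                 min_stance_frames = min_stance_frames,
                 min_stance_duration = min_stance_duration,
                 registration_delay = registration_delay,
                 resample_n = as.integer(resample_n),
                 ci_level = ci_level,
                 segmentation_axis = match.arg(segmentation_axis),
                 gap_fill = gap_fill, max_gap = max_gap,
                 recipes = recipes, joint_pairs = joint_pairs),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Only scalar settings are serialized; recipes and joint pairs can be
#' overridden by name in the YAML under `recipes:` / `joint_pairs:`.
#'
#' @param path YAML file path.
#' @return For `read_config`, a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  cfg <- do.call(pipeline_config, args[setdiff(names(args), c("recipes", "joint_pairs"))])
  if (!is.null(y$joint_pairs))
    for (j in names(y$joint_pairs)) cfg$joint_pairs[[j]] <- unlist(y$joint_pairs[[j]])
  cfg
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  scal <- config[c("kinematic_cutoff", "kinetic_cutoff", "stance_threshold",
                   "min_stance_frames", "min_stance_duration",
                   "registration_delay", "resample_n", "ci_level",
                   "segmentation_axis", "gap_fill", "max_gap")]
  scal$joint_pairs <- config$joint_pairs
  yaml::write_yaml(scal, path)
  invisible(path)
}

#' Draw the gait models of a full study design
#'
#' Emulates the study layout (subjects x shoes x repeated trials, two devices
#' recorded simultaneously): subject-level anthropometrics and gait style,
#' a systematic shoe effect, and trial-level variation in pose, timing,
#' loading and sensor noise. All draws flow from `seed`.
#'
#' @param n_subjects,n_trials design size (default 10 subjects x 5 trials,
#'   shoes A and B).
#' @param shoes shoe conditions.
#' @param base a [gait_model()] supplying the population means.
#' @param insole_bias multiplicative insole factor applied to every trial.
#' @param seed integer seed.
#' @return List of lists with elements `model` and `meta` (one per
#'   subject x shoe x trial).
#' @export
design_models <- function(n_subjects = 10L, n_trials = 5L, shoes = c("A", "B"),
                          base = gait_model(), insole_bias = 1, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  out <- list()
  for (si in seq_len(n_subjects)) {
    mass <- rtrunc(1, base$body_mass, 12, 45, 110)
    fl <- rtrunc(1, base$foot_length, 0.012, 0.21, 0.29)
    pk <- c(rtrunc(1, base$force_profile$peaks[1L], 0.04, 0.9, 1.3),
            rtrunc(1, base$force_profile$peaks[2L], 0.04, 0.9, 1.3))
    valley <- rtrunc(1, base$force_profile$valley, 0.03, 0.6, 0.95)
    ang0 <- stats::rnorm(1, base$progression_angle, 0.05)
    met_x0 <- stats::rnorm(1, -0.010, 0.003)
    for (shoe in shoes) {
      # shoe B: stiffer sole spreads forefoot load and shifts it laterally
      sxm <- if (shoe == "B") 0.023 else 0.020
      met_x <- met_x0 + if (shoe == "B") 0.005 else 0
      valley_s <- valley + if (shoe == "B") 0.02 else 0
      for (tr in seq_len(n_trials)) {
        blobs <- default_blobs(fl)
        blobs$sx[blobs$name == "met"] <- sxm
        blobs$cx[blobs$name == "met"] <- met_x
        m <- gait_model(
          foot_length = fl, body_mass = mass,
          stance_duration = rtrunc(1, base$stance_duration, 0.03, 0.6, 0.8),
          rate = base$rate,
          force_profile = list(peaks = pk + stats::rnorm(2, 0, 0.015),
                               peak_times = base$force_profile$peak_times,
                               valley = valley_s),
          blobs = blobs,
          progression_angle = ang0 + stats::rnorm(1, 0, 0.02),
          foot_position = base$foot_position + stats::rnorm(2, 0, 0.005),
          noise_sd = base$noise_sd, insole_bias = insole_bias,
          seed = sample.int(.Machine$integer.max, 1L))
        out[[length(out) + 1L]] <- list(
          model = m,
          meta = trial_meta(sprintf("S%02d", si), mass, shoe, "platform", tr))
      }
    }
  }
  out
}

#' Simulate a dataset directory (or in-memory trial list)
#'
#' @param models output of [design_models()] (or a single [gait_model()]).
#' @param out_dir optional directory; each trial is written with
#'   [write_trial()] under `subject_shoe_trial/`.
#' @return List of [gait_trial()] objects (invisibly when writing).
#' @export
simulate_dataset <- function(models, out_dir = NULL) {
  if (inherits(models, "gait_model"))
    models <- list(list(model = models,
                        meta = trial_meta("S1", models$body_mass, "A", "platform", 1L)))
  trials <- lapply(models, function(mm) simulate_trial(mm$model, mm$meta)$trial)
  names(trials) <- vapply(models, function(mm)
    sprintf("%s_%s_t%d", mm$meta$subject_id, mm$meta$shoe, mm$meta$trial_index),
    character(1))
  if (!is.null(out_dir)) {
    for (nm in names(trials)) write_trial(trials[[nm]], file.path(out_dir, nm))
    return(invisible(trials))
  }
  trials
}

#' Process a set of trials with both devices
#'
#' Fits [foot_kinetics()] per trial per device, collects the long-format
#' parameter table and per-subject mean curves, and logs rejected trials.
#'
#' @param trials list of [gait_trial()] objects.
#' @param config a [pipeline_config()].
#' @param devices devices to analyze (default both).
#' @param out_dir optional results directory for [write_results()] plus a
#'   config snapshot.
#' @return List of class `processed_design`: `fits`, `params`, `rejected`,
#'   `manifest` (when written).
#' @export
process_trials <- function(trials, config = pipeline_config(),
                           devices = c("platform", "insole"), out_dir = NULL) {
  fits <- list()
  rejected <- character(0)
  for (nm in names(trials) %||% as.character(seq_along(trials))) {
    for (dv in devices) {
      fit <- tryCatch(foot_kinetics(trials[[nm]], dv, config),
                      footkinetics_trial_rejected_error = function(e) NULL)
      if (is.null(fit)) {
        rejected <- c(rejected, paste(nm, dv))
      } else {
        fits[[paste(nm, dv, sep = "_")]] <- fit
      }
    }
  }
  if (!length(fits)) abort("no trial could be processed", "runtime_error")
  params <- build_parameter_table(fits)
  out <- structure(list(fits = fits, params = params, rejected = rejected),
                   class = "processed_design")
  if (!is.null(out_dir)) {
    curves <- lapply(fits, function(f) f$moments$ankle)
    out$manifest <- write_results(curves, params, out_dir)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

#' @export
print.processed_design <- function(x, ...) {
  cat(sprintf("<processed_design> %d fits, %d parameter rows, %d rejected\n",
              length(x$fits), nrow(x$params), length(x$rejected)))
  invisible(x)
}

#' Per-subject mean moment curves for one joint/motion/device/shoe
#'
#' Averages trials within subject first (subjects are the unit of analysis),
#' ready for [mean_ci_curves()] / [plot_mean_ci()].
#'
#' @param design a `processed_design`.
#' @param joint,motion,device,shoe selection (`shoe = NULL` pools shoes).
#' @return `n_subjects x 101` matrix.
#' @export
subject_mean_curves <- function(design, joint, motion, device, shoe = NULL) {
  sel <- Filter(function(f) f$device == device &&
                  (is.null(shoe) || f$meta$shoe == shoe), design$fits)
  subj <- vapply(sel, function(f) f$meta$subject_id, character(1))
  mats <- lapply(sel, function(f)
    if (motion == "force") f$forces[[joint]] else f$moments[[joint]]$values[, motion])
  us <- sort(unique(subj))
  out <- t(vapply(us, function(s)
    colMeans(do.call(rbind, mats[subj == s])), numeric(length(mats[[1L]]))))
  rownames(out) <- us
  out
}

#' Device-agreement report
#'
#' Compares the per-trial curve parameters between platform and insole:
#' relative difference of the device mean peaks (% of the platform mean) and
#' two-way mixed-effects ICCs in two layouts: the device pair as k = 2
#' "raters" on per-subject means (default report), and test-retest
#' reliability across the k = 5 repeated trials of the device difference
#' layout. Abduction/adduction parameters are computed upstream but excluded
#' here, as their moments are near zero throughout stance.
#'
#' @param params long-format parameter table ([build_parameter_table()]).
#' @param parameters which parameters to report per motion (default: MaxVal
#'   and TMax for forces and flexion moments, MinVal and TMin for
#'   inversion/eversion).
#' @return Data frame with one row per joint x motion x parameter: device
#'   means, percent difference, ICC consistency/agreement and p-value.
#' @export
compare_devices <- function(params, parameters = NULL) {
  if (!all(c("platform", "insole") %in% params$device))
    abort("parameter table must contain both devices", "design_mismatch_error")
  sel <- data.frame(
    motion = c("force", "force", "dfpf", "dfpf", "inev", "inev"),
    parameter = c("MaxVal", "TMax", "MaxVal", "TMax", "MinVal", "TMin"))
  if (!is.null(parameters)) sel <- sel[sel$parameter %in% parameters, ]
  rows <- list()
  for (j in unique(params$joint)) {
    for (r in seq_len(nrow(sel))) {
      sub <- params[params$joint == j & params$motion == sel$motion[r] &
                      params$parameter == sel$parameter[r], ]
      if (!nrow(sub)) next
      # per-subject means per device, matched
      agg <- stats::aggregate(value ~ subject + device, sub, mean)
      wide <- stats::reshape(agg, idvar = "subject", timevar = "device",
                             direction = "wide")
      if (anyNA(wide) || nrow(wide) < 2L)
        abort("devices do not share the design", "design_mismatch_error")
      m_p <- mean(wide$value.platform)
      m_i <- mean(wide$value.insole)
      ic <- icc(as.matrix(wide[, c("value.platform", "value.insole")]))
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, motion = sel$motion[r], parameter = sel$parameter[r],
        platform_mean = m_p, insole_mean = m_i,
        pct_diff = 100 * (m_i - m_p) / abs(m_p),
        icc_consistency = ic$consistency, icc_agreement = ic$agreement,
        p_value = ic$p_value)
    }
  }
  do.call(rbind, rows)
}

#' Test-retest ICC across repeated trials
#'
#' Reliability of one parameter across the k repeated trials (default the
#' study's 5), per device, using subjects as rows.
#'
#' @param params long-format parameter table.
#' @param joint,motion,parameter selection.
#' @param device device to assess.
#' @return An [icc()] result.
#' @export
test_retest_icc <- function(params, joint, motion, parameter,
                            device = "platform") {
  sub <- params[params$joint == joint & params$motion == motion &
                  params$parameter == parameter & params$device == device, ]
  # pool shoes: average the two shoe conditions per trial index
  agg <- stats::aggregate(value ~ subject + trial, sub, mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "trial",
                         direction = "wide")
  icc(as.matrix(wide[, -1L]))
}
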