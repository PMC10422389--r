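# Curve descriptors, aggregation, the long-format parameter table and
# intraclass correlation coefficients.

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) Butterworth coefficients applied forward and
#' backward, so the net gain at the cutoff is 0.5 and no phase shift (hence no
#' shift of peak timings) is introduced. The series is extended by odd
#' reflection over 3 x order samples at each end and each pass is started from
#' its steady state, so constants pass through exactly.
#'
#' Cutoffs at or above the Nyquist frequency are clipped to 0.95 x Nyquist
#' with a warning: a 50 Hz cutoff at 100 Hz sampling is the identity in
#' intent but ill-posed in design.
#'
#' @param x numeric series.
#' @param fs sampling frequency (Hz).
#' @param fc cutoff frequency (Hz).
#' @param order filter order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, fs, fc, order = 4L) {
  if (fc <= 0) abort("cutoff must be positive", "validation_error")
  nyq <- fs / 2
  if (fc >= nyq) {
    warnf("cutoff %g Hz is at/above Nyquist (%g Hz); clipping to %g Hz",
          fc, nyq, 0.95 * nyq)
    fc <- 0.95 * nyq
  }
  np <- 3L * order
  n <- length(x)
  if (n <= np + 1L)
    abort(sprintf("series of length %d is shorter than the %d-sample padding", n, np),
          "validation_error")
  bf <- signal::butter(order, fc / nyq)
  b <- bf$b; a <- bf$a
  g <- sum(b) / sum(a)                       # DC gain (1 for a low-pass)
  xe <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  pass <- function(z) signal::filter(b, a, z,
                                     init.x = rep(z[1L], length(b) - 1L),
                                     init.y = rep(z[1L] * g, length(a) - 1L))
  y <- pass(xe)
  y <- rev(pass(rev(y)))
  y[(np + 1L):(np + n)]
}

#' Resample a stance interval to a fixed percent-stance grid
#'
#' Linear interpolation at `n` equispaced stations over `[onset, offset]`;
#' the endpoints are reproduced exactly.
#'
#' @param x numeric series (whole trial).
#' @param onset,offset stance frame bounds (1-based, `offset > onset`).
#' @param n number of stations (default 101, i.e. 0..100% stance).
#' @return Numeric vector of length `n`.
#' @export
resample_stance <- function(x, onset, offset, n = 101L) {
  if (n < 2L) abort("n must be at least 2", "validation_error")
  if (offset <= onset) abort("offset must exceed onset", "validation_error")
  stats::approx(seq_along(x), x, xout = seq(onset, offset, length.out = n))$y
}

#' Peak descriptors of a percent-stance curve
#'
#' @param curve numeric curve sampled at 0..100% stance.
#' @return Named list: `max_val`, `t_max` (% stance of the first global
#'   maximum), `min_val`, `t_min`.
#' @export
extract_params <- function(curve) {
  if (anyNA(curve) || any(!is.finite(curve)))
    abort("curve must be finite", "validation_error")
  n <- length(curve)
  pct <- seq(0, 100, length.out = n)
  list(max_val = max(curve), t_max = pct[which.max(curve)],
       min_val = min(curve), t_min = pct[which.min(curve)])
}

#' Pointwise mean and confidence-interval curves across subjects
#'
#' Subjects are the unit of analysis (average trials within subject first);
#' the interval is the pointwise t-based CI
#' `mean +/- t(n-1, 1-(1-level)/2) * sd / sqrt(n)`.
#'
#' @param curves `n_subjects x n_points` matrix of per-subject mean curves.
#' @param level confidence level (default 0.95).
#' @return List with `mean`, `lower`, `upper` (each length `n_points`) and `n`.
#' @export
mean_ci_curves <- function(curves, level = 0.95) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2L) abort("at least two subjects are required", "validation_error")
  m <- colMeans(curves)
  se <- apply(curves, 2L, stats::sd) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  list(mean = m, lower = m - tq * se, upper = m + tq * se, n = n)
}

#' Long-format curve-parameter table of a processed design
#'
#' One row per subject x shoe x device x trial x joint x motion x parameter.
#' For the standard 10 x 2 x 2 x 5 design this is 200 values per parameter.
#'
#' @param fits list of `foot_kinetics` fits (one per trial x device).
#' @return Data frame with columns `subject, shoe, device, trial, joint,
#'   motion, parameter, value`.
#' @export
build_parameter_table <- function(fits) {
  rows <- lapply(fits, function(fit) {
    stopifnot(inherits(fit, "foot_kinetics"))
    p <- coef(fit)
    data.frame(subject = fit$meta$subject_id, shoe = fit$meta$shoe,
               device = fit$device, trial = fit$meta$trial_index,
               joint = p$joint, motion = p$motion, parameter = p$parameter,
               value = p$value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  key <- tab[, c("subject", "shoe", "device", "trial", "joint", "motion", "parameter")]
  if (anyDuplicated(key))
    abort("duplicate design cell in parameter table", "validation_error")
  tab
}

#' Intraclass correlation coefficients from a two-way model
#'
#' Two-way mixed-effects ICCs from the ANOVA mean squares of an
#' `n x k` ratings matrix (subjects x measurements): consistency
#' ICC(3,k) = (MS_R - MS_E) / MS_R and absolute agreement
#' ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n) for mean ratings;
#' the single-rating forms ICC(3,1)/ICC(2,1) when `mean_rating = FALSE`.
#' The p-value is the F-test of between-subject variance,
#' `F = MS_R / MS_E` on `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param ratings `n x k` numeric matrix without missing cells.
#' @param mean_rating report the reliability of the mean of the k
#'   measurements (default TRUE).
#' @return Object of class `icc_result`: `consistency`, `agreement`, `k`,
#'   `n`, `p_value`, `ms` (the mean squares).
#' @export
icc <- function(ratings, mean_rating = TRUE) {
  x <- as.matrix(ratings)
  if (anyNA(x)) abort("ratings must have no missing cells", "validation_error")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 measurements",
                              "validation_error")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ss_r <- k * sum((rm_ - gm)^2)
  ss_c <- n * sum((cm - gm)^2)
  ss_t <- sum((x - gm)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ms_r < 1e-14) {
    warnf("zero between-subject variance; ICC undefined, returning 0")
    cons <- agr <- 0
    p <- 1
  } else {
    if (mean_rating) {
      cons <- (ms_r - ms_e) / ms_r
      agr <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
    } else {
      cons <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
      agr <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
    }
    p <- stats::pf(ms_r / ms_e, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(consistency = cons, agreement = agr, k = k, n = n,
                 mean_rating = mean_rating, p_value = p,
                 ms = c(rows = ms_r, cols = ms_c, error = ms_e)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (two-way mixed, %s): consistency %.3f, agreement %.3f (n=%d, k=%d, p=%.3g)\n",
              if (x$mean_rating) "mean-rating" else "single-rating",
              x$consistency, x$agreement, x$n, x$k, x$p_value))
  invisible(x)
}
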