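#' Construct a normalized stance-phase curve
#'
#' A stance curve is one stance phase resampled onto an equally spaced
#' percent-of-stance grid (0 to 100 inclusive), with forces in body-weight
#' (BW) units, i.e. newtons divided by body mass times g = 9.81 m/s^2.
#'
#' @param subject_id,trial_id,cohort identifiers as in [raw_trial_record()].
#' @param grid percent-of-stance grid, equally spaced, strictly increasing,
#'   length >= 2 (default pipelines use 101 points).
#' @param y_ml,y_ap,y_v force channels in BW units, same length as `grid`.
#' @param stance_duration stance duration in seconds.
#' @return an object of class `stance_curve`.
#' @export
stance_curve <- function(subject_id, trial_id, cohort, grid,
                         y_ml, y_ap, y_v, stance_duration) {
  p <- length(grid)
  if (p < 2) grf_error("grid must have at least 2 points", "grf_argument_error")
  if (length(y_ml) != p || length(y_ap) != p || length(y_v) != p)
    grf_error("channel length must match grid length", "grf_data_error")
  dg <- diff(grid)
  if (any(dg <= 0) || (p > 2 && max(abs(dg - dg[1])) > 1e-9 * max(dg)))
    grf_error("grid must be strictly increasing and equally spaced",
              "grf_data_error")
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id), cohort = cohort,
                 grid = as.numeric(grid), y_ml = as.numeric(y_ml),
                 y_ap = as.numeric(y_ap), y_v = as.numeric(y_v),
                 stance_duration = as.numeric(stance_duration)),
            class = "stance_curve")
}

#' @export
print.stance_curve <- function(x, ...) {
  cat(sprintf("<stance_curve> %s / %s (%s): %d points, %.3f s stance, peak vGRF %.3f BW\n",
              x$subject_id, x$trial_id, x$cohort, length(x$grid),
              x$stance_duration, max(x$y_v)))
  invisible(x)
}

#' Detect the stance phase in a raw trial
#'
#' Finds the longest contiguous run of samples whose vertical force exceeds
#' `threshold_fraction` of body weight, after discarding runs shorter than
#' `min_duration`. Ties between equal-length maximal runs are broken toward
#' the earliest start.
#'
#' @param record a [raw_trial_record()].
#' @param threshold_fraction contact threshold as a fraction of body weight,
#'   in (0, 1); default 0.05 (5% BW, standard force-plate practice).
#' @param min_duration minimum contact duration in seconds (default 0.05).
#' @return integer vector `c(start, end)`: 1-based start index (inclusive) and
#'   end index (exclusive) of the stance window.
#' @export
detect_stance <- function(record, threshold_fraction = 0.05,
                          min_duration = 0.05) {
  stopifnot(inherits(record, "raw_trial_record"))
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    grf_error("threshold_fraction must lie in (0, 1)", "grf_argument_error")
  thr <- threshold_fraction * record$body_mass * GRAVITY
  above <- record$f_v > thr
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / record$sample_rate >= min_duration)
  if (!any(keep))
    grf_error("no above-threshold contact of sufficient duration found",
              "grf_no_contact_error")
  i <- which(keep)[which.max(r$lengths[keep])]  # which.max: earliest on ties
  c(start = starts[i], end = ends[i] + 1L)
}

#' Resample a stance window onto a percent-stance grid in body-weight units
#'
#' Linearly interpolates each force channel onto `n_points` equally spaced
#' times spanning the window, divides by body weight (mass x 9.81), and labels
#' the result with a 0-100% stance grid. Linear (not spline) interpolation is
#' used: it is monotone and overshoot-free on force data.
#'
#' @param record a [raw_trial_record()].
#' @param window integer `c(start, end)` as returned by [detect_stance()]
#'   (start inclusive, end exclusive), length >= 2 samples.
#' @param n_points number of grid points (>= 2; default 101, the gait-analysis
#'   convention of 1% steps).
#' @return a [stance_curve()].
#' @export
normalize_time <- function(record, window, n_points = 101) {
  stopifnot(inherits(record, "raw_trial_record"))
  start <- as.integer(window[[1]]); end <- as.integer(window[[2]])
  n <- length(record$t)
  if (start < 1 || end > n + 1 || end - start < 2)
    grf_error("window outside record or shorter than 2 samples",
              "grf_index_error")
  if (n_points < 2)
    grf_error("n_points must be >= 2", "grf_argument_error")
  idx <- start:(end - 1)
  tt <- record$t[idx]
  xout <- seq(tt[1], tt[length(tt)], length.out = n_points)
  bw <- record$body_mass * GRAVITY
  interp <- function(y)
    stats::approx(tt, y[idx], xout = xout, method = "linear")$y / bw
  stance_curve(record$subject_id, record$trial_id, record$cohort,
               grid = seq(0, 100, length.out = n_points),
               y_ml = interp(record$f_ml), y_ap = interp(record$f_ap),
               y_v = interp(record$f_v),
               stance_duration = tt[length(tt)] - tt[1])
}

#' Quality-control a stance curve
#'
#' Checks that the curve looks like a plausible single stance: duration within
#' `duration_range`, peak vertical force within `peak_v_range` (BW), and all
#' channels finite. QC never raises on content; it reports every violated
#' rule.
#'
#' @param curve a [stance_curve()].
#' @param duration_range allowed stance duration in seconds.
#' @param peak_v_range allowed peak vertical force in BW.
#' @return list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing).
#' @export
qc_trial <- function(curve, duration_range = c(0.2, 2.0),
                     peak_v_range = c(0.5, 2.0)) {
  stopifnot(inherits(curve, "stance_curve"))
  reasons <- character()
  if (!all(is.finite(c(curve$y_ml, curve$y_ap, curve$y_v))))
    reasons <- c(reasons, "non-finite sample")
  d <- curve$stance_duration
  if (!is.finite(d) || d < duration_range[1])
    reasons <- c(reasons, "stance duration below minimum")
  else if (d > duration_range[2])
    reasons <- c(reasons, "stance duration above maximum")
  pk <- suppressWarnings(max(curve$y_v, na.rm = TRUE))
  if (!is.finite(pk) || pk < peak_v_range[1])
    reasons <- c(reasons, "peak vertical force below minimum")
  else if (pk > peak_v_range[2])
    reasons <- c(reasons, "peak vertical force above maximum")
  list(pass = length(reasons) == 0, reasons = reasons)
}
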