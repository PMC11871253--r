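check_pair <- function(h, p, min_n = 1) {
  if (length(h) != length(p))
    grf_error("series must have equal length", "grf_argument_error")
  if (length(h) < min_n)
    grf_error(paste0("series must have at least ", min_n, " points"),
              "grf_argument_error")
  if (any(!is.finite(h)) || any(!is.finite(p)))
    grf_error("series must be finite", "grf_data_error")
}

#' Trend similarity: Pearson correlation between two gait curves
#'
#' The Pearson correlation coefficient of a reference series `h` and a patient
#' series `p` sampled on the same grid: the centered cross-product divided by
#' the product of the centered norms. It measures how well the shapes of the
#' two waveforms agree, independent of their magnitudes.
#'
#' @param h,p numeric series of equal length (>= 3), finite, each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson_trend <- function(h, p) {
  check_pair(h, p, min_n = 3)
  hc <- h - mean(h)
  pc <- p - mean(p)
  den2 <- sum(hc^2) * sum(pc^2)
  if (den2 == 0)
    grf_error("correlation undefined: a series has zero variance",
              "grf_undefined_correlation_error")
  sum(hc * pc) / sqrt(den2)
}

#' Scale dissimilarity: symmetric mean absolute percentage error (SMAPE)
#'
#' The mean over grid points of `|h_i - p_i|` divided by `(|h_i| + |p_i|)/2`.
#' The symmetric denominator resolves the scaling disparity between subjects
#' and avoids division by zero except when both values are exactly zero; such
#' zero-pairs contribute 0 to the mean (the limit of the summand along equal
#' values).
#'
#' @param h,p numeric series of equal length, finite.
#' @return SMAPE in \[0, 2\]; 0 means identical magnitudes.
#' @export
smape <- function(h, p) {
  check_pair(h, p)
  den <- (abs(h) + abs(p)) / 2
  term <- abs(h - p) / den
  term[den == 0] <- 0
  mean(term)
}

#' Scale similarity: SMAPE score
#'
#' `1 - smape(h, p)`: 1 means identical magnitudes, values toward -1 mean
#' maximal magnitude discrepancy (sign-opposed series).
#'
#' @inheritParams smape
#' @return score in \[-1, 1\].
#' @export
smape_score <- function(h, p) 1 - smape(h, p)

#' Six-variable similarity feature vector for one trial
#'
#' Computes, per GRF axis (ML, AP, V), the trend similarity
#' ([pearson_trend()]) and the scale similarity ([smape_score()]) of a
#' reference-scaled patient curve against the healthy template, yielding the
#' six clustering features.
#'
#' @param curve a [stance_curve()] already passed through
#'   [apply_reference_scaling()].
#' @param template a `grf_reference` on the same grid.
#' @return one-row data.frame with `subject_id`, `trial_id`, `cohort` and the
#'   metric columns `r_ml, r_ap, r_v, s_ml, s_ap, s_v`.
#' @export
feature_vector <- function(curve, template) {
  stopifnot(inherits(curve, "stance_curve"),
            inherits(template, "grf_reference"))
  if (!same_grid(curve$grid, template$grid))
    grf_error("curve grid does not match the reference grid",
              "grf_alignment_error")
  out <- data.frame(subject_id = curve$subject_id, trial_id = curve$trial_id,
                    cohort = curve$cohort, stringsAsFactors = FALSE)
  for (ax in c("ml", "ap", "v")) {
    h <- template[[paste0("h_", ax)]]
    p <- curve[[paste0("y_", ax)]]
    wrap <- function(f) tryCatch(f(h, p), error = function(e)
      stop(errorCondition(paste0("axis ", ax, ": ", conditionMessage(e)),
                          class = class(e))))
    out[[paste0("r_", ax)]] <- wrap(pearson_trend)
    out[[paste0("s_", ax)]] <- wrap(smape_score)
  }
  out
}

#' Average trial feature vectors into one subject-level vector
#'
#' Componentwise arithmetic mean of the six metrics across a subject's trials,
#' mirroring how per-subject tables average the experimental trials.
#'
#' @param trial_vectors data.frame of feature vectors (rows) from a single
#'   subject, as produced by [feature_vector()].
#' @return one-row data.frame with `trial_id = "mean"`.
#' @export
subject_features <- function(trial_vectors) {
  if (!is.data.frame(trial_vectors) || nrow(trial_vectors) < 1)
    grf_error("need at least one trial vector", "grf_argument_error")
  if (length(unique(trial_vectors$subject_id)) != 1)
    grf_error("trial vectors come from more than one subject",
              "grf_argument_error")
  out <- trial_vectors[1, , drop = FALSE]
  out$trial_id <- "mean"
  for (cn in .feature_cols) out[[cn]] <- mean(trial_vectors[[cn]])
  rownames(out) <- NULL
  out
}
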