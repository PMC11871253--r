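# small constructed fixtures used across test files

make_record <- function(f_v, f_ml = NULL, f_ap = NULL, body_mass = 60,
                        sample_rate = 100, cohort = "patient",
                        subject_id = "S1", trial_id = "T1") {
  n <- length(f_v)
  if (is.null(f_ml)) f_ml <- rep(1, n)
  if (is.null(f_ap)) f_ap <- rep(-1, n)
  raw_trial_record(subject_id, trial_id, cohort, body_mass,
                   t = (seq_len(n) - 1) / sample_rate,
                   f_ml = f_ml, f_ap = f_ap, f_v = f_v,
                   sample_rate = sample_rate)
}

make_curve <- function(y_v, y_ml = NULL, y_ap = NULL, subject_id = "S1",
                       trial_id = "T1", cohort = "patient",
                       stance_duration = 0.7) {
  p <- length(y_v)
  if (is.null(y_ml)) y_ml <- rep(0.05, p)
  if (is.null(y_ap)) y_ap <- sin(seq(-pi, pi, length.out = p)) * 0.2
  stance_curve(subject_id, trial_id, cohort,
               grid = seq(0, 100, length.out = p),
               y_ml = y_ml, y_ap = y_ap, y_v = y_v,
               stance_duration = stance_duration)
}

# deterministic simulated curves on the default grid
sim_curves <- function(n, seed, cohort = "healthy", params = NULL,
                       noise_sd = 0.01) {
  if (is.null(params)) params <- default_waveform_params()
  withr_seed <- function(code) { set.seed(seed); code }
  out <- vector("list", n)
  set.seed(seed)
  for (i in seq_len(n)) {
    rec <- simulate_trial(params, 60 + 2 * i, sprintf("%s%02d", cohort, i),
                          "T1", cohort = cohort, noise_sd = noise_sd)
    out[[i]] <- normalize_time(rec, detect_stance(rec))
  }
  out
}

feature_matrix <- function(df) as.matrix(df[, c("r_ml", "r_ap", "r_v",
                                                "s_ml", "s_ap", "s_v")])
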