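# ---- Synthetic stance-phase GRF cohorts ----
#
# The simulator produces the statistical structure the pipeline assumes:
# a healthy template waveform, subject- and trial-level variability, smooth
# measurement noise, and two patient archetypes — one that preserves waveform
# shape but attenuates magnitude (limited range of motion / insufficient
# force, "Group-1-like") and one that distorts waveform shape (atypical,
# defensive gait, "Group-2-like").

#' Default stance-phase waveform parameters
#'
#' Textbook-typical GRF morphology in body-weight (BW) units over percent of
#' stance: an M-shaped vertical component (two ~1.1 BW peaks near 25% and 75%
#' with a mid-stance valley), a biphasic anterior-posterior component (braking
#' negative then propulsive positive, crossing zero mid-stance), and a
#' low-amplitude medial-lateral bump.
#'
#' @param v_peak1,v_peak2 vertical peak heights (BW).
#' @param v_valley mid-stance valley term depth (BW).
#' @param v_pos1,v_pos2 vertical peak positions (% stance).
#' @param v_width vertical bump width (% stance).
#' @param ap_brake,ap_prop braking and propulsive amplitudes (BW).
#' @param ap_zero zero-crossing position (% stance).
#' @param ap_width AP bump width (% stance).
#' @param ml_amp,ml_pos,ml_width medial-lateral bump amplitude (BW), position
#'   and width (% stance).
#' @param stance_duration stance duration (s).
#' @return an object of class `waveform_params`.
#' @export
default_waveform_params <- function(v_peak1 = 1.1, v_peak2 = 1.1,
                                    v_valley = 0.05, v_pos1 = 25, v_pos2 = 75,
                                    v_width = 17,
                                    ap_brake = 0.18, ap_prop = 0.18,
                                    ap_zero = 50, ap_width = 12,
                                    ml_amp = 0.1, ml_pos = 40, ml_width = 15,
                                    stance_duration = 0.7) {
  p <- list(v_peak1 = v_peak1, v_peak2 = v_peak2, v_valley = v_valley,
            v_pos1 = v_pos1, v_pos2 = v_pos2, v_width = v_width,
            ap_brake = ap_brake, ap_prop = ap_prop, ap_zero = ap_zero,
            ap_width = ap_width, ml_amp = ml_amp, ml_pos = ml_pos,
            ml_width = ml_width, stance_duration = stance_duration)
  if (p$v_pos1 >= p$v_pos2)
    grf_error("vertical peak positions must be ordered", "grf_argument_error")
  if (p$stance_duration < 0.2 || p$stance_duration > 2)
    grf_error("stance_duration must lie in [0.2, 2] s", "grf_argument_error")
  structure(p, class = "waveform_params")
}

# smoothstep taper to 0 over the first/last `edge` fraction of stance (~7 ms
# at default duration, a heel-strike-like transient), so all channels vanish
# at foot-strike and toe-off
stance_envelope <- function(u, edge = 0.01) {
  s <- function(z) { z <- pmin(pmax(z, 0), 1); z * z * (3 - 2 * z) }
  s(u / (100 * edge)) * s((100 - u) / (100 * edge))
}

gauss_bump <- function(u, pos, width) exp(-0.5 * ((u - pos) / width)^2)

#' Evaluate the noise-free healthy GRF waveform
#'
#' @param params a [default_waveform_params()] object.
#' @param t_frac percent-of-stance points in \[0, 100\] (vectorized).
#' @return list with components `f_ml`, `f_ap`, `f_v` in BW units.
#' @export
healthy_waveform <- function(params = default_waveform_params(), t_frac) {
  stopifnot(inherits(params, "waveform_params"))
  if (any(t_frac < 0 | t_frac > 100))
    grf_error("t_frac must lie in [0, 100]", "grf_argument_error")
  u <- as.numeric(t_frac)
  env <- stance_envelope(u)
  f_v <- (params$v_peak1 * gauss_bump(u, params$v_pos1, params$v_width) +
          params$v_peak2 * gauss_bump(u, params$v_pos2, params$v_width) -
          params$v_valley * gauss_bump(u, 50, 12)) * env
  f_ap <- (-params$ap_brake * gauss_bump(u, params$ap_zero - 25,
                                         params$ap_width) +
           params$ap_prop * gauss_bump(u, params$ap_zero + 25,
                                       params$ap_width)) * env
  f_ml <- params$ml_amp * gauss_bump(u, params$ml_pos, params$ml_width) * env
  list(f_ml = f_ml, f_ap = f_ap, f_v = f_v)
}

# multiplicative jitter on amplitudes, additive jitter (in % stance) on
# positions, used for both between-subject and between-trial variability
jitter_params <- function(params, sd) {
  amps <- c("v_peak1", "v_peak2", "v_valley", "ap_brake", "ap_prop", "ml_amp")
  for (f in amps) params[[f]] <- params[[f]] * (1 + stats::rnorm(1, 0, sd))
  pos <- c("v_pos1", "v_pos2", "ap_zero", "ml_pos")
  for (f in pos)
    params[[f]] <- min(max(params[[f]] + stats::rnorm(1, 0, 100 * sd), 5), 95)
  if (params$v_pos1 >= params$v_pos2) {
    mid <- (params$v_pos1 + params$v_pos2) / 2
    params$v_pos1 <- mid - 1; params$v_pos2 <- mid + 1
  }
  params$stance_duration <-
    min(max(params$stance_duration * (1 + stats::rnorm(1, 0, sd)), 0.25), 1.9)
  params
}

# band-limited measurement noise: white noise convolved with a 30 ms Gaussian
# window normalized to unit energy, so the output SD equals `sd`
smooth_noise <- function(n, sd, sample_rate) {
  if (sd <= 0) return(numeric(n))
  L <- max(3L, as.integer(round(0.03 * sample_rate)))
  k <- exp(-0.5 * ((seq_len(L) - (L + 1) / 2) / (L / 4))^2)
  k <- k / sqrt(sum(k^2))
  w <- stats::rnorm(n + L - 1, 0, sd)
  as.numeric(stats::convolve(w, k, conj = TRUE, type = "filter"))
}

#' Simulate one force-plate trial
#'
#' Evaluates the waveform at `sample_rate` over the stance duration (after
#' trial-level parameter jitter), converts to newtons via the subject's body
#' mass, adds temporally smooth noise, and flanks the stance with 0.1 s of
#' zero-force padding so stance detection is exercised. Consumes the current
#' RNG stream; seed the caller for reproducibility.
#'
#' @param params subject-level [default_waveform_params()].
#' @param body_mass subject body mass (kg).
#' @param subject_id,trial_id,cohort,side record metadata.
#' @param trial_sd trial-to-trial parameter jitter scale (default 0.015).
#' @param noise_sd smooth noise SD in BW units (default 0.01).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @return a [raw_trial_record()].
#' @export
simulate_trial <- function(params, body_mass, subject_id, trial_id,
                           cohort = "healthy", side = "left",
                           trial_sd = 0.015, noise_sd = 0.01,
                           sample_rate = 1000) {
  tp <- jitter_params(params, trial_sd)
  n_st <- as.integer(round(tp$stance_duration * sample_rate)) + 1L
  u <- 100 * (seq_len(n_st) - 1) / (n_st - 1)
  w <- healthy_waveform(tp, u)
  n_pad <- as.integer(round(0.1 * sample_rate))
  pad <- numeric(n_pad)
  n_tot <- n_st + 2L * n_pad
  bw <- body_mass * GRAVITY
  chan <- function(y) (c(pad, y, pad) +
                       smooth_noise(n_tot, noise_sd, sample_rate)) * bw
  raw_trial_record(subject_id = subject_id, trial_id = trial_id,
                   cohort = cohort, body_mass = body_mass, side = side,
                   sample_rate = sample_rate,
                   t = (seq_len(n_tot) - 1) / sample_rate,
                   f_ml = chan(w$f_ml), f_ap = chan(w$f_ap),
                   f_v = chan(w$f_v))
}

#' Cohort specification for the simulator
#'
#' Defaults define the reference study conditions: 8 healthy, 8 Group-1-like
#' and 8 Group-2-like subjects with 3 trials each; Group-1 subjects keep the
#' healthy waveform shape but attenuate all amplitudes by `group1_scale`;
#' Group-2 subjects shift their waveform features later in stance by
#' `group2_phase_shift` percent and warp the ratio of the two vertical peaks
#' by `group2_peak_warp`.
#'
#' @param n_healthy,n_group1,n_group2 subject counts (>= 0).
#' @param trials_per_subject trials per subject (default 3).
#' @param group1_scale amplitude attenuation in (0, 1\] (default 0.6).
#' @param group2_phase_shift phase shift in % stance (default 10).
#' @param group2_peak_warp vertical peak-ratio warp in \[0, 1) (default 0.3).
#' @param subject_sd,trial_sd between-subject / between-trial parameter jitter
#'   scales (defaults 0.01 and 0.015: archetype effects dominate subject-level
#'   spread, which sits at or below trial-level spread, so per-trial feature
#'   vectors form one cluster per archetype rather than one per subject).
#' @param noise_sd smooth noise SD in BW (default 0.01).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param body_mass_mean,body_mass_sd body-mass distribution in kg (defaults
#'   65 and 10, clamped to \[45, 95\]).
#' @param seed integer seed; identical spec and seed give bit-identical
#'   cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 8, n_group1 = 8, n_group2 = 8,
                        trials_per_subject = 3, group1_scale = 0.6,
                        group2_phase_shift = 10, group2_peak_warp = 0.3,
                        subject_sd = 0.01, trial_sd = 0.015, noise_sd = 0.01,
                        sample_rate = 1000, body_mass_mean = 65,
                        body_mass_sd = 10, seed = 0) {
  if (min(n_healthy, n_group1, n_group2) < 0 || trials_per_subject < 1)
    grf_error("counts must be >= 0 and trials_per_subject >= 1",
              "grf_argument_error")
  if (group1_scale <= 0 || group1_scale > 1)
    grf_error("group1_scale must lie in (0, 1]", "grf_argument_error")
  structure(list(n_healthy = n_healthy, n_group1 = n_group1,
                 n_group2 = n_group2, trials_per_subject = trials_per_subject,
                 group1_scale = group1_scale,
                 group2_phase_shift = group2_phase_shift,
                 group2_peak_warp = group2_peak_warp,
                 subject_sd = subject_sd, trial_sd = trial_sd,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
                 seed = seed),
            class = "cohort_spec")
}

apply_archetype <- function(params, archetype, spec) {
  if (archetype == "group1") {
    for (f in c("v_peak1", "v_peak2", "v_valley", "ap_brake", "ap_prop",
                "ml_amp"))
      params[[f]] <- params[[f]] * spec$group1_scale
  } else if (archetype == "group2") {
    params$v_peak1 <- params$v_peak1 * (1 + spec$group2_peak_warp)
    params$v_peak2 <- params$v_peak2 * (1 - spec$group2_peak_warp)
    for (f in c("v_pos1", "v_pos2", "ap_zero", "ml_pos"))
      params[[f]] <- min(max(params[[f]] + spec$group2_phase_shift, 5), 95)
    if (params$v_pos1 >= params$v_pos2) params$v_pos2 <- params$v_pos1 + 2
  }
  params
}

#' Simulate a full gait cohort
#'
#' Draws subject-level waveform parameters around the healthy template,
#' applies the archetype transform for patient subjects, and simulates
#' `trials_per_subject` trials per subject. Truth labels are returned
#' alongside the data so recovery tests never re-derive them.
#'
#' @param spec a [cohort_spec()].
#' @param template healthy template parameters
#'   (default [default_waveform_params()]).
#' @return list with `trials` (list of [raw_trial_record()]) and `truth`
#'   (data.frame `subject_id`, `archetype`, `body_mass`).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            template = default_waveform_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- data.frame(
    subject_id = c(sprintf("H%02d", seq_len(spec$n_healthy)),
                   sprintf("P1_%02d", seq_len(spec$n_group1)),
                   sprintf("P2_%02d", seq_len(spec$n_group2))),
    archetype = rep(c("healthy", "group1", "group2"),
                    c(spec$n_healthy, spec$n_group1, spec$n_group2)),
    stringsAsFactors = FALSE)
  trials <- list()
  masses <- numeric(nrow(plan))
  with_seed(spec$seed, {
    for (i in seq_len(nrow(plan))) {
      masses[i] <- min(max(stats::rnorm(1, spec$body_mass_mean,
                                        spec$body_mass_sd), 45), 95)
      sp <- apply_archetype(jitter_params(template, spec$subject_sd),
                            plan$archetype[i], spec)
      cohort <- if (plan$archetype[i] == "healthy") "healthy" else "patient"
      for (tr in seq_len(spec$trials_per_subject))
        trials[[length(trials) + 1]] <-
          simulate_trial(sp, masses[i], plan$subject_id[i],
                         sprintf("T%d", tr), cohort = cohort,
                         trial_sd = spec$trial_sd, noise_sd = spec$noise_sd,
                         sample_rate = spec$sample_rate)
    }
  })
  plan$body_mass <- masses
  list(trials = trials, truth = plan)
}

#' Write a simulated cohort to a directory of trial CSVs
#'
#' One CSV per trial (via [write_grf_trial()]) plus a `manifest.tsv` with the
#' truth table.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$trials)
    write_grf_trial(rec, file.path(dir, paste0(rec$subject_id, "_",
                                               rec$trial_id, ".csv")))
  utils::write.table(cohort$truth, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
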