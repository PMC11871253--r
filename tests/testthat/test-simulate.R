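test_that("the healthy waveform has the expected stance-phase morphology", {
  p <- default_waveform_params()
  g <- seq(0, 100, 1)
  w <- healthy_waveform(p, g)
  # all channels vanish at foot-strike and toe-off
  for (ch in w) expect_true(all(abs(ch[c(1, 101)]) < 1e-3))
  # M-shaped vertical: peak in [1.0, 1.3] BW, non-negative everywhere
  expect_gte(max(w$f_v), 1.0)
  expect_lte(max(w$f_v), 1.3)
  expect_true(all(w$f_v >= 0))
  # biphasic AP: negative braking then positive propulsion, one sign change
  interior <- w$f_ap[abs(w$f_ap) > 1e-6]
  expect_lt(interior[1], 0)
  expect_gt(interior[length(interior)], 0)
  expect_equal(sum(diff(sign(interior)) != 0), 1)
  # braking and propulsive impulses balance within 10% of braking impulse
  brake <- abs(sum(pmin(w$f_ap, 0)))
  prop <- sum(pmax(w$f_ap, 0))
  expect_lt(abs(prop - brake) / brake, 0.1)
  expect_error(healthy_waveform(p, c(-1, 50)), class = "grf_argument_error")
})

test_that("simulated trials are deterministic given the RNG state", {
  p <- default_waveform_params()
  set.seed(101)
  r1 <- simulate_trial(p, 70, "S1", "T1")
  set.seed(101)
  r2 <- simulate_trial(p, 70, "S1", "T1")
  expect_identical(r1, r2)
  # whole cohorts are bit-identical for identical spec + seed
  c1 <- simulate_cohort(cohort_spec(n_healthy = 2, n_group1 = 1,
                                    n_group2 = 1, seed = 9))
  c2 <- simulate_cohort(cohort_spec(n_healthy = 2, n_group1 = 1,
                                    n_group2 = 1, seed = 9))
  expect_identical(c1, c2)
  # empty cohort
  c0 <- simulate_cohort(cohort_spec(n_healthy = 0, n_group1 = 0,
                                    n_group2 = 0))
  expect_length(c0$trials, 0)
  expect_equal(nrow(c0$truth), 0)
})

test_that("simulated trials pass QC and stance detection finds the padding", {
  set.seed(102)
  rec <- simulate_trial(default_waveform_params(), 65, "S1", "T1")
  cu <- normalize_time(rec, detect_stance(rec))
  expect_true(qc_trial(cu)$pass)
  # noise-free trial: detection recovers the 0.1 s padding within 2 samples
  set.seed(103)
  rec0 <- simulate_trial(default_waveform_params(), 65, "S1", "T1",
                         trial_sd = 0, noise_sd = 0)
  win <- detect_stance(rec0)
  n_pad <- 100
  n_stance <- length(rec0$t) - 2 * n_pad
  expect_lte(abs(win[["start"]] - (n_pad + 1)), 2)
  expect_lte(abs(win[["end"]] - (n_pad + n_stance)), 2)
})

test_that("a noise-free trial scores as identical to its own reference", {
  p <- default_waveform_params()
  set.seed(104)
  recs <- lapply(1:3, function(i)
    simulate_trial(p, 50 + 10 * i, paste0("H", i), "T1",
                   trial_sd = 0, noise_sd = 0))
  curves <- lapply(recs, function(r) normalize_time(r, detect_stance(r)))
  tmpl <- build_reference(curves[1:2])
  fv <- feature_vector(apply_reference_scaling(curves[[3]], tmpl), tmpl)
  expect_equal(as.numeric(feature_matrix(fv)), rep(1, 6), tolerance = 0.02)
})

test_that("patient archetypes produce the intended feature signatures", {
  sim <- simulate_cohort(cohort_spec(seed = 0))
  curves <- lapply(sim$trials, function(r) normalize_time(r, detect_stance(r)))
  healthy <- Filter(function(cu) cu$cohort == "healthy", curves)
  tmpl <- build_reference(healthy)
  feats <- do.call(rbind, lapply(curves, function(cu)
    feature_vector(apply_reference_scaling(cu, tmpl), tmpl)))
  feats$archetype <- sim$truth$archetype[match(feats$subject_id,
                                               sim$truth$subject_id)]
  mean_by <- function(col) tapply(feats[[col]], feats$archetype, mean)
  # Group-1-like: shape preserved (high trend), magnitude attenuated
  expect_gt(mean_by("r_ml")[["group1"]], 0.8)
  expect_gt(mean_by("r_ap")[["group1"]], 0.8)
  for (s in c("s_ml", "s_ap", "s_v"))
    expect_lt(mean_by(s)[["group1"]], mean_by(s)[["healthy"]])
  # Group-2-like: shape distorted relative to Group 1
  expect_lt(mean_by("r_ml")[["group2"]], mean_by("r_ml")[["group1"]])
})

test_that("increasing shape distortion never increases trend similarity", {
  r_trend <- vapply(c(5, 10, 15, 20), function(shift) {
    sim <- simulate_cohort(cohort_spec(n_healthy = 4, n_group1 = 0,
                                       n_group2 = 4, trials_per_subject = 2,
                                       group2_phase_shift = shift, seed = 5))
    curves <- lapply(sim$trials, function(r)
      normalize_time(r, detect_stance(r)))
    healthy <- Filter(function(cu) cu$cohort == "healthy", curves)
    tmpl <- build_reference(healthy)
    pats <- Filter(function(cu) cu$cohort == "patient", curves)
    f <- do.call(rbind, lapply(pats, function(cu)
      feature_vector(apply_reference_scaling(cu, tmpl), tmpl)))
    mean(c(f$r_ml, f$r_ap, f$r_v))
  }, numeric(1))
  expect_true(all(diff(r_trend) <= 0))
})

test_that("cohorts serialize to a directory that reads back faithfully", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cohort_spec(n_healthy = 1, n_group1 = 1,
                                     n_group2 = 0, trials_per_subject = 2,
                                     seed = 3))
  write_cohort(sim, dir)
  files <- list.files(dir, pattern = "\\.csv$")
  expect_length(files, 4)
  rec <- read_grf_trial(file.path(dir, files[1]))
  orig <- sim$trials[[which(vapply(sim$trials, function(r)
    paste0(r$subject_id, "_", r$trial_id, ".csv"), "") == files[1])]]
  expect_equal(rec$f_v, orig$f_v)
  expect_equal(rec$body_mass, orig$body_mass)
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(manifest), 2)
})
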