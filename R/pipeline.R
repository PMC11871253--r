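#' Pipeline configuration
#'
#' Declares inputs and settings for [run_pipeline()]: either a directory of
#' trial CSVs (`input_dir`) or a simulation spec (`cohort`), plus the
#' preprocessing and clustering settings.
#'
#' @param input_dir directory of trial CSV files, or `NULL`.
#' @param cohort a [cohort_spec()], or `NULL` (exactly one of the two must be
#'   given).
#' @param threshold_fraction,min_duration stance detection settings
#'   (see [detect_stance()]).
#' @param n_points percent-stance grid size (default 101).
#' @param k_range candidate component counts for BIC selection; a single value
#'   skips selection and fits that K directly.
#' @param covariance_type,n_init,var_floor,tol,max_iter mixture settings
#'   (see [gmm_fit()]).
#' @param seed integer seed controlling clustering initialization.
#' @param unit `"trial"` (cluster per-trial feature vectors; default, enables
#'   the intra-validation consistency check) or `"subject_mean"`.
#' @param include_healthy also cluster healthy subjects' feature vectors
#'   (default `FALSE`: patients only).
#' @param output_dir if non-`NULL`, serialized outputs are written here.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL,
                            threshold_fraction = 0.05, min_duration = 0.05,
                            n_points = 101, k_range = 1:5,
                            covariance_type = "diag", n_init = 10, seed = 0,
                            var_floor = 1e-4, tol = 1e-6, max_iter = 500,
                            unit = c("trial", "subject_mean"),
                            include_healthy = FALSE, output_dir = NULL) {
  if (is.null(input_dir) == is.null(cohort))
    grf_error("give exactly one of input_dir or cohort", "grf_argument_error")
  structure(list(input_dir = input_dir, cohort = cohort,
                 threshold_fraction = threshold_fraction,
                 min_duration = min_duration, n_points = n_points,
                 k_range = k_range, covariance_type = covariance_type,
                 n_init = n_init, seed = seed, var_floor = var_floor,
                 tol = tol, max_iter = max_iter, unit = match.arg(unit),
                 include_healthy = include_healthy, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full gait classification pipeline
#'
#' Orchestrates measurement intake, preprocessing, reference building,
#' similarity quantification, mixture clustering and reporting:
#' read or simulate trials; extract and normalize the stance phase; QC each
#' curve; build the healthy reference template (healthy subjects are scored
#' against leave-one-out templates to avoid self-comparison bias); compute the
#' six-variable feature vectors; select K by BIC (unless `k_range` is a single
#' value) and fit the mixture; canonicalize group names; check per-subject
#' trial consistency; run the k-means/elbow/silhouette cross-check; and
#' summarize group-level curve ensembles. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return a list report: `features` (per-trial), `subject_features`,
#'   `reference`, `selection` (BIC table or NULL), `model`, `clusters`,
#'   `assignments` (data.frame subject/trial/group), `consistency`,
#'   `kmeans`, `elbow`, `silhouette`, `ensembles`, `qc_failures`,
#'   `skipped_inputs`, and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  skipped <- character()
  if (!is.null(config$cohort)) {
    sim <- simulate_cohort(config$cohort)
    records <- sim$trials
    truth <- sim$truth
  } else {
    paths <- list.files(config$input_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    records <- list()
    for (p in paths) {
      rec <- tryCatch(read_grf_trial(p), error = function(e) {
        message("skipping unreadable input: ", p, " (",
                conditionMessage(e), ")")
        NULL
      })
      if (is.null(rec)) skipped <- c(skipped, p) else
        records[[length(records) + 1]] <- rec
    }
  }
  if (!length(records))
    grf_error("no readable trials", "grf_data_error")

  curves <- list()
  qc_failures <- list()
  for (rec in records) {
    curve <- tryCatch({
      win <- detect_stance(rec, config$threshold_fraction,
                           config$min_duration)
      normalize_time(rec, win, config$n_points)
    }, error = function(e) {
      message("trial ", rec$subject_id, "/", rec$trial_id,
              " dropped: ", conditionMessage(e))
      NULL
    })
    if (is.null(curve)) next
    qc <- qc_trial(curve)
    if (!qc$pass) {
      message("trial ", rec$subject_id, "/", rec$trial_id, " failed QC: ",
              paste(qc$reasons, collapse = "; "))
      qc_failures[[length(qc_failures) + 1]] <-
        data.frame(subject_id = rec$subject_id, trial_id = rec$trial_id,
                   reasons = paste(qc$reasons, collapse = "; "))
      next
    }
    curves[[length(curves) + 1]] <- curve
  }
  qc_failures <- if (length(qc_failures)) do.call(rbind, qc_failures) else NULL

  is_healthy <- vapply(curves, function(cu) cu$cohort == "healthy", TRUE)
  healthy <- curves[is_healthy]
  patients <- curves[!is_healthy]
  if (length(unique(vapply(healthy, `[[`, "", "subject_id"))) < 2)
    grf_error("need at least 2 healthy subjects to build the reference",
              "grf_data_error")
  if (!length(patients) && !config$include_healthy)
    grf_error("no patient trials survived preprocessing/QC", "grf_data_error")
  template <- build_reference(healthy)

  feats <- lapply(patients, function(cu)
    feature_vector(apply_reference_scaling(cu, template), template))
  # healthy subjects: leave-one-subject-out template
  h_subj <- vapply(healthy, `[[`, "", "subject_id")
  for (s in unique(h_subj)) {
    rest <- healthy[h_subj != s]
    if (length(unique(vapply(rest, `[[`, "", "subject_id"))) < 2) {
      message("healthy subject ", s,
              " skipped: too few others for a leave-one-out reference")
      next
    }
    loo <- build_reference(rest)
    for (cu in healthy[h_subj == s])
      feats[[length(feats) + 1]] <-
        feature_vector(apply_reference_scaling(cu, loo), loo)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  subj_features <- do.call(rbind, lapply(split(features, features$subject_id),
                                         subject_features))
  rownames(subj_features) <- NULL

  cl_rows <- if (config$include_healthy) features else
    features[features$cohort == "patient", , drop = FALSE]
  if (config$unit == "subject_mean")
    cl_rows <- do.call(rbind, lapply(split(cl_rows, cl_rows$subject_id),
                                     subject_features))
  X <- as.matrix(cl_rows[, .feature_cols])

  selection <- NULL
  if (length(config$k_range) > 1) {
    selection <- select_k(X, k_range = config$k_range,
                          covariance_type = config$covariance_type,
                          n_init = config$n_init, seed = config$seed,
                          tol = config$tol, max_iter = config$max_iter,
                          var_floor = config$var_floor)
    K <- selection$K
    model <- selection$models[[as.character(K)]]
  } else {
    K <- config$k_range[1]
    model <- gmm_fit(X, K, covariance_type = config$covariance_type,
                     n_init = config$n_init, seed = config$seed,
                     tol = config$tol, max_iter = config$max_iter,
                     var_floor = config$var_floor)
  }
  clusters <- canonicalize_groups(gmm_assign(model, X), r_ml = cl_rows$r_ml)
  assignments <- data.frame(subject_id = cl_rows$subject_id,
                            trial_id = cl_rows$trial_id,
                            cohort = cl_rows$cohort,
                            group = clusters$group,
                            stringsAsFactors = FALSE)
  consistency <- subject_consistency(assignments$group,
                                     assignments$subject_id)

  km <- if (K >= 1 && nrow(X) > K)
    kmeans_fit(X, K, n_init = config$n_init, seed = config$seed) else NULL
  elbow <- tryCatch(elbow_table(X, config$k_range, n_init = config$n_init,
                                seed = config$seed),
                    error = function(e) NULL)
  sil <- if (K >= 2) tryCatch(silhouette_score(X, clusters$labels),
                              error = function(e) NA_real_) else NA_real_

  # group-level curve ensembles per axis (healthy + canonical patient groups)
  subj_group <- stats::setNames(consistency$modal_group,
                                consistency$subject_id)
  grp_of <- function(cu) {
    if (cu$cohort == "healthy" && !config$include_healthy) return("Healthy")
    g <- subj_group[[cu$subject_id]]
    if (is.null(g)) NA_character_ else g
  }
  groups <- vapply(curves, grp_of, "")
  ensembles <- lapply(c(ml = "ml", ap = "ap", v = "v"), function(ax) {
    Y <- do.call(rbind, lapply(curves, `[[`, paste0("y_", ax)))
    ensemble_stats(Y, groups, grid = template$grid)
  })

  report <- list(features = features, subject_features = subj_features,
                 reference = template, selection = selection, model = model,
                 clusters = clusters, assignments = assignments,
                 consistency = consistency, kmeans = km, elbow = elbow,
                 silhouette = sil, ensembles = ensembles,
                 qc_failures = qc_failures, skipped_inputs = skipped,
                 truth = truth, seed = config$seed)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(report$features, file.path(dir, "features.tsv"),
                      full_precision = TRUE)
  write_feature_table(report$subject_features,
                      file.path(dir, "subject_features.tsv"),
                      full_precision = TRUE)
  utils::write.table(report$assignments, file.path(dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$consistency, file.path(dir, "consistency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$selection))
    utils::write.table(report$selection$table, file.path(dir, "bic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$elbow))
    utils::write.table(report$elbow, file.path(dir, "elbow.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference(report$reference, file.path(dir, "reference.csv"))
  model <- report$model
  dump <- list(K = model$K, weights = model$weights,
               means = model$means, covariances = model$covariances,
               covariance_type = model$covariance_type,
               log_likelihood = model$log_likelihood,
               n_params = model$n_params, converged = model$converged,
               n_iter = model$n_iter, seed = report$seed,
               silhouette = report$silhouette)
  jsonlite::write_json(dump, file.path(dir, "model.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Pointwise ensemble statistics for groups of curves
#'
#' For each group with at least two curves, the pointwise mean and the t-based
#' 95% confidence half-width `SD/sqrt(n) * t(0.975, n-1)`. Groups with a
#' single curve are excluded with a warning. Intervals are pointwise and
#' descriptive; no multiplicity correction across grid points.
#'
#' @param Y matrix of curves (one row per curve) or list of equal-length
#'   numeric vectors.
#' @param groups group label per curve.
#' @param grid x-axis values (default column index).
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `group`, `x`, `mean`, `ci_halfwidth`, `n`.
#' @export
ensemble_stats <- function(Y, groups, grid = NULL, conf = 0.95) {
  if (is.list(Y) && !is.matrix(Y)) Y <- do.call(rbind, Y)
  Y <- as.matrix(Y)
  if (length(groups) != nrow(Y))
    grf_error("groups must have one label per curve", "grf_argument_error")
  if (is.null(grid)) grid <- seq_len(ncol(Y))
  keep <- !is.na(groups)
  Y <- Y[keep, , drop = FALSE]; groups <- groups[keep]
  out <- list()
  for (g in unique(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    n <- nrow(Yg)
    if (n < 2) {
      warning("group '", g, "' has fewer than 2 curves; excluded")
      next
    }
    se <- apply(Yg, 2, stats::sd) / sqrt(n)
    out[[length(out) + 1]] <-
      data.frame(group = g, x = grid, mean = colMeans(Yg),
                 ci_halfwidth = se * stats::qt(1 - (1 - conf) / 2, n - 1),
                 n = n, stringsAsFactors = FALSE)
  }
  if (!length(out))
    grf_error("no group has at least 2 curves", "grf_argument_error")
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
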