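#' Construct a raw force-plate trial record
#'
#' A trial record holds one force-plate recording of the three ground reaction
#' force (GRF) components during (at least) one stance phase: medial-lateral
#' (`f_ml`), anterior-posterior (`f_ap`) and vertical (`f_v`), in newtons, on a
#' common time base in seconds. Sign conventions: vertical positive upward,
#' anterior-posterior positive in the direction of progression (braking
#' negative), medial-lateral positive lateral. The conventions are documented,
#' not enforced; all downstream similarity metrics are convention-agnostic as
#' long as they are applied consistently.
#'
#' @param subject_id,trial_id character identifiers.
#' @param cohort `"healthy"` or `"patient"`.
#' @param body_mass subject body mass in kg (> 0, finite).
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param f_ml,f_ap,f_v force channels in newtons, same length as `t` (>= 2).
#' @param side `"left"` or `"right"`; the affected side for patients.
#' @param sample_rate sampling rate in Hz; if `NULL`, inferred from the median
#'   time step. Sample spacing must be consistent with it within 1%.
#' @return an object of class `raw_trial_record`.
#' @export
raw_trial_record <- function(subject_id, trial_id, cohort, body_mass,
                             t, f_ml, f_ap, f_v,
                             side = "left", sample_rate = NULL) {
  cohort <- match.arg(cohort, c("healthy", "patient"))
  side <- match.arg(side, c("left", "right"))
  if (!is.finite(body_mass) || body_mass <= 0)
    grf_error("body_mass must be a finite positive number (kg)",
              "grf_metadata_error")
  n <- length(t)
  if (n < 2 || length(f_ml) != n || length(f_ap) != n || length(f_v) != n)
    grf_error("all force channels must have the same length >= 2 as t",
              "grf_data_error")
  dt <- diff(t)
  if (any(dt <= 0))
    grf_error("time vector must be strictly increasing", "grf_data_error")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    grf_error("sample_rate must be positive", "grf_metadata_error")
  if (any(abs(dt * sample_rate - 1) > 0.01))
    grf_error("sample spacing inconsistent with sample_rate (beyond 1%)",
              "grf_data_error")
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 cohort = cohort, body_mass = body_mass, side = side,
                 sample_rate = sample_rate,
                 t = as.numeric(t), f_ml = as.numeric(f_ml),
                 f_ap = as.numeric(f_ap), f_v = as.numeric(f_v)),
            class = "raw_trial_record")
}

#' @export
print.raw_trial_record <- function(x, ...) {
  cat(sprintf("<raw_trial_record> %s / %s (%s, %s side)\n",
              x$subject_id, x$trial_id, x$cohort, x$side))
  cat(sprintf("  %d samples @ %.6g Hz, %.3f s; body mass %.6g kg\n",
              length(x$t), x$sample_rate, diff(range(x$t)), x$body_mass))
  invisible(x)
}

# canonical column names in trial CSV files, and accepted aliases
.trial_cols <- c(time = "time_s", f_ml = "f_ml_N", f_ap = "f_ap_N",
                 f_v = "f_v_N")

#' Read a force-plate trial from CSV
#'
#' Trial files are plain CSV with columns `time_s`, `f_ml_N`, `f_ap_N`,
#' `f_v_N` (bare names `time`, `f_ml`, `f_ap`, `f_v` are also accepted) and an
#' optional metadata header of `# key: value` comment lines. Units are taken
#' as seconds and newtons.
#'
#' @param path path to a trial CSV file.
#' @param metadata named list overriding/supplying metadata (`subject_id`,
#'   `trial_id`, `cohort`, `body_mass`, `side`, `sample_rate`). Entries given
#'   here win over the file header.
#' @return a [raw_trial_record()].
#' @export
read_grf_trial <- function(path, metadata = list()) {
  if (!file.exists(path))
    grf_error(paste0("file not found: ", path), "grf_io_error")
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta[names(metadata)] <- metadata
  body <- lines[!is_meta]
  if (!length(body))
    grf_error("no CSV content in file", "grf_format_error")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  col <- function(key) {
    hits <- which(names(df) %in% c(.trial_cols[[key]], key))
    if (!length(hits))
      grf_error(paste0("missing required column: ", key), "grf_format_error")
    as.numeric(df[[hits[1]]])
  }
  need <- function(key, default = NULL) {
    if (!is.null(meta[[key]])) return(meta[[key]])
    if (!is.null(default)) return(default)
    grf_error(paste0("missing required metadata: ", key), "grf_metadata_error")
  }
  bm <- as.numeric(need("body_mass"))
  if (!is.finite(bm) || bm <= 0)
    grf_error("body_mass must be a positive number", "grf_metadata_error")
  sr <- meta[["sample_rate"]]
  raw_trial_record(subject_id = need("subject_id"),
                   trial_id = need("trial_id",
                                   sub("\\.csv$", "", basename(path))),
                   cohort = need("cohort"), body_mass = bm,
                   side = need("side", "left"),
                   sample_rate = if (is.null(sr)) NULL else as.numeric(sr),
                   t = col("time"), f_ml = col("f_ml"),
                   f_ap = col("f_ap"), f_v = col("f_v"))
}

#' Write a force-plate trial to CSV
#'
#' Writes the metadata header plus the four-channel CSV at full double
#' precision, so [read_grf_trial()] inverts it exactly.
#'
#' @param record a [raw_trial_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grf_trial <- function(record, path) {
  stopifnot(inherits(record, "raw_trial_record"))
  vals <- c(record$f_ml, record$f_ap, record$f_v)
  if (any(!is.finite(vals)) || any(!is.finite(record$t)))
    grf_error("record contains non-finite samples; refusing to write",
              "grf_data_error")
  num <- function(x) formatC(x, digits = 17, format = "g", width = 1)
  hdr <- sprintf("# %s: %s",
                 c("subject_id", "trial_id", "cohort", "body_mass", "side",
                   "sample_rate"),
                 c(record$subject_id, record$trial_id, record$cohort,
                   num(record$body_mass), record$side,
                   num(record$sample_rate)))
  rows <- paste(num(record$t), num(record$f_ml), num(record$f_ap),
                num(record$f_v), sep = ",")
  out <- c(hdr, paste(.trial_cols, collapse = ","), rows)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) grf_error(paste0("cannot write file: ", path), "grf_io_error")
  invisible(path)
}

#' Bundled hip osteoarthritis similarity feature table
#'
#' Loads the packaged per-subject feature table from a published 16-patient
#' hip osteoarthritis force-plate study: trend similarity (Pearson correlation
#' against the healthy reference, per GRF axis), scale similarity (SMAPE
#' score, per axis), the mixture-model group each subject was assigned to, and
#' the Kellgren-Lawrence radiographic grade. Each row is the average of that
#' subject's three gait trials; values are as printed, at two decimals.
#'
#' @return a data.frame with 16 rows and columns `subject_id`, `r_ml`, `r_ap`,
#'   `r_v`, `s_ml`, `s_ap`, `s_v`, `group`, `kl_grade`.
#' @export
load_hip_oa_features <- function() {
  path <- system.file("extdata", "hip_oa_features.tsv", package = "grfclust",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$kl_grade <- as.integer(df$kl_grade)
  df
}

.feature_cols <- c("r_ml", "r_ap", "r_v", "s_ml", "s_ap", "s_v")

#' Write a similarity feature table
#'
#' Writes a TSV with the six similarity metrics rounded to two decimals
#' (matching the presentation of the bundled clinical table), plus `group` and
#' `kl_grade` when present. With `full_precision = TRUE` an extra block of
#' `*_full` columns preserves the unrounded values.
#'
#' @param rows data.frame with a `subject_id` column and the six metric
#'   columns `r_ml, r_ap, r_v, s_ml, s_ap, s_v`.
#' @param path output path.
#' @param full_precision append full-precision columns.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path, full_precision = FALSE) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    grf_error("rows must be a nonempty data.frame", "grf_argument_error")
  miss <- setdiff(c("subject_id", .feature_cols), names(rows))
  if (length(miss))
    grf_error(paste0("missing feature columns: ", paste(miss, collapse = ", ")),
              "grf_argument_error")
  out <- data.frame(subject_id = rows$subject_id)
  for (cn in c("trial_id", "cohort"))
    if (cn %in% names(rows)) out[[cn]] <- rows[[cn]]
  for (cn in .feature_cols) out[[cn]] <- sprintf("%.2f", rows[[cn]])
  for (cn in c("group", "kl_grade"))
    if (cn %in% names(rows)) out[[cn]] <- rows[[cn]]
  if (full_precision)
    for (cn in .feature_cols)
      out[[paste0(cn, "_full")]] <- formatC(rows[[cn]], digits = 17,
                                            format = "g", width = 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity feature table written by [write_feature_table()]
#'
#' @param path path to a TSV feature table.
#' @return a data.frame; `*_full` columns, when present, replace the rounded
#'   metric columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cn in .feature_cols) {
    full <- paste0(cn, "_full")
    if (full %in% names(df)) {
      df[[cn]] <- as.numeric(df[[full]])
      df[[full]] <- NULL
    } else df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
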