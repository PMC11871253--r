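same_grid <- function(g1, g2, tol = 1e-9) {
  length(g1) == length(g2) && max(abs(g1 - g2)) <= tol
}

#' Build the healthy reference template
#'
#' Pools healthy stance curves into a per-axis mean curve and standardizes it
#' so that, on each axis, the mean absolute value of the healthy mean curve
#' over the stance grid equals 1. The per-axis scaling factor
#' `c_a = 1 / mean(|pointwise mean|)` is stored and must be applied to patient
#' curves (see [apply_reference_scaling()]) so patient and reference live on
#' the same standardized scale. Mean-absolute scaling (rather than peak or
#' RMS) is used because the anterior-posterior axis crosses zero.
#'
#' Pointwise standard deviations are computed across the scaled curves.
#'
#' @param healthy_curves list of [stance_curve()]s on identical grids
#'   (length >= 2).
#' @return an object of class `grf_reference` with fields `grid`, `h_ml`,
#'   `h_ap`, `h_v` (scaled mean curves), `sd_ml`, `sd_ap`, `sd_v`, scaling
#'   factors `c_ml`, `c_ap`, `c_v`, and `n_subjects`.
#' @export
build_reference <- function(healthy_curves) {
  if (!is.list(healthy_curves) || length(healthy_curves) < 2)
    grf_error("need at least 2 healthy curves", "grf_argument_error")
  stopifnot(all(vapply(healthy_curves, inherits, TRUE, "stance_curve")))
  grid <- healthy_curves[[1]]$grid
  for (cu in healthy_curves)
    if (!same_grid(cu$grid, grid))
      grf_error("healthy curves are not on a common grid",
                "grf_alignment_error")
  tmpl <- list(grid = grid, n_subjects = length(healthy_curves))
  for (ax in c("ml", "ap", "v")) {
    Y <- do.call(rbind, lapply(healthy_curves, `[[`, paste0("y_", ax)))
    m <- colMeans(Y)
    ma <- mean(abs(m))
    if (ma == 0)
      grf_error(paste0("axis ", ax, ": healthy mean is identically zero"),
                "grf_degenerate_reference_error")
    ca <- 1 / ma
    tmpl[[paste0("c_", ax)]] <- ca
    tmpl[[paste0("h_", ax)]] <- m * ca
    tmpl[[paste0("sd_", ax)]] <- apply(Y * ca, 2, stats::sd)
  }
  structure(tmpl, class = "grf_reference")
}

#' @export
print.grf_reference <- function(x, ...) {
  cat(sprintf("<grf_reference> %d healthy subjects, %d grid points\n",
              x$n_subjects, length(x$grid)))
  cat(sprintf("  scaling factors: c_ml=%.4g c_ap=%.4g c_v=%.4g\n",
              x$c_ml, x$c_ap, x$c_v))
  invisible(x)
}

#' Scale a curve onto the reference's standardized scale
#'
#' Multiplies each axis of a stance curve by the template's per-axis scaling
#' factor, so it is directly comparable with the template curves under both
#' similarity metrics.
#'
#' @param curve a [stance_curve()] on the template's grid.
#' @param template a `grf_reference` from [build_reference()].
#' @return the scaled [stance_curve()].
#' @export
apply_reference_scaling <- function(curve, template) {
  stopifnot(inherits(curve, "stance_curve"),
            inherits(template, "grf_reference"))
  if (!same_grid(curve$grid, template$grid))
    grf_error("curve grid does not match the reference grid",
              "grf_alignment_error")
  for (ax in c("ml", "ap", "v"))
    curve[[paste0("y_", ax)]] <-
      curve[[paste0("y_", ax)]] * template[[paste0("c_", ax)]]
  curve
}

#' Serialize a reference template to CSV
#'
#' Writes grid, mean and SD curves as CSV with the scaling factors and subject
#' count in a comment header; [read_reference()] inverts it.
#'
#' @param template a `grf_reference`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(template, path) {
  stopifnot(inherits(template, "grf_reference"))
  num <- function(x) formatC(x, digits = 17, format = "g", width = 1)
  hdr <- c(sprintf("# c_ml: %s", num(template$c_ml)),
           sprintf("# c_ap: %s", num(template$c_ap)),
           sprintf("# c_v: %s", num(template$c_v)),
           sprintf("# n_subjects: %d", template$n_subjects))
  cols <- c("grid", "h_ml", "h_ap", "h_v", "sd_ml", "sd_ap", "sd_v")
  rows <- do.call(paste, c(lapply(cols, function(cn) num(template[[cn]])),
                           sep = ","))
  writeLines(c(hdr, paste(cols, collapse = ","), rows), path)
  invisible(path)
}

#' Read a reference template written by [write_reference()]
#'
#' @param path path to a reference CSV.
#' @return a `grf_reference`.
#' @export
read_reference <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*(\\w+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  structure(c(as.list(df), list(c_ml = meta$c_ml, c_ap = meta$c_ap,
                                c_v = meta$c_v,
                                n_subjects = as.integer(meta$n_subjects))),
            class = "grf_reference")
}
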