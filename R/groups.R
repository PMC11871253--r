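#' Canonical group names for a cluster result
#'
#' Renames mixture components `Group1, Group2, ...` by descending member
#' count; ties are broken by ascending mean ML trend similarity when `r_ml`
#' is supplied (so the lower-trend cluster gets the smaller group number),
#' otherwise by ascending component index.
#'
#' @param result a `grf_clusters` from [gmm_assign()].
#' @param r_ml optional numeric vector (one value per clustered point) of ML
#'   trend similarity, used only for tie-breaking.
#' @return the `grf_clusters` with `canonical_names` (component -> group name
#'   bijection) and `group` (canonical name per point) filled in.
#' @export
canonicalize_groups <- function(result, r_ml = NULL) {
  stopifnot(inherits(result, "grf_clusters"))
  K <- result$K
  counts <- tabulate(result$labels, nbins = K)
  tie <- if (is.null(r_ml)) seq_len(K) else
    vapply(seq_len(K), function(k) {
      v <- r_ml[result$labels == k]
      if (length(v)) mean(v) else Inf
    }, numeric(1))
  ord <- order(-counts, tie, seq_len(K))
  nm <- character(K)
  nm[ord] <- paste0("Group", seq_len(K))
  result$canonical_names <- stats::setNames(nm, seq_len(K))
  result$group <- nm[result$labels]
  result
}

#' @export
print.grf_clusters <- function(x, ...) {
  cat(sprintf("<grf_clusters> %d points in %d components\n",
              length(x$labels), x$K))
  if (!is.null(x$group)) print(table(x$group)) else print(table(x$labels))
  invisible(x)
}

#' Per-subject trial-consistency report
#'
#' For each subject, the modal group across its trials, the fraction of trials
#' assigned to that group, and whether all trials agree. The global
#' `all_consistent` flag is the intra-validation check: a trustworthy
#' clustering should put every trial of one subject in the same group.
#'
#' @param groups character/integer vector of per-trial group assignments.
#' @param subject_ids vector of the same length mapping trials to subjects.
#' @return data.frame with columns `subject_id`, `modal_group`, `fraction`,
#'   `consistent`, plus attribute `all_consistent`.
#' @export
subject_consistency <- function(groups, subject_ids) {
  if (length(groups) != length(subject_ids) || !length(groups))
    grf_error("groups and subject_ids must be nonempty and equal length",
              "grf_argument_error")
  subs <- unique(subject_ids)
  rows <- lapply(subs, function(s) {
    g <- groups[subject_ids == s]
    tab <- sort(table(g), decreasing = TRUE)
    data.frame(subject_id = s, modal_group = names(tab)[1],
               fraction = as.numeric(tab[1]) / length(g),
               consistent = length(tab) == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_consistent") <- all(out$consistent)
  out
}
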