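# k-means cross-check for the mixture clustering: Lloyd iterations (via
# stats::kmeans) from in-package k-means++ seeds, plus the elbow and
# silhouette diagnostics used to corroborate the BIC choice of K.

#' k-means clustering from k-means++ starts
#'
#' Runs `n_init` restarts of Lloyd's algorithm seeded by k-means++ and keeps
#' the solution with the lowest inertia (total within-cluster sum of squares).
#'
#' @param X numeric matrix (n x d).
#' @param K number of clusters (<= n).
#' @param n_init number of restarts (default 10).
#' @param seed integer seed or `NULL`.
#' @return list with `centers` (K x d), `labels` (length n) and `inertia`.
#' @export
kmeans_fit <- function(X, K, n_init = 10, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K < 1 || K > n)
    grf_error("need 1 <= K <= n", "grf_argument_error")
  distinct <- unique(X)
  if (nrow(distinct) <= K) {
    # fewer distinct points than clusters: each distinct row is a center
    labels <- match(apply(X, 1, paste, collapse = "\r"),
                    apply(distinct, 1, paste, collapse = "\r"))
    centers <- distinct[c(seq_len(nrow(distinct)),
                          rep(1, K - nrow(distinct))), , drop = FALSE]
    return(list(centers = centers, labels = labels, inertia = 0))
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(X, K)
      km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  list(centers = unname(best$centers), labels = as.integer(best$cluster),
       inertia = best$tot.withinss)
}

#' Elbow table: k-means inertia as a function of K
#'
#' @inheritParams kmeans_fit
#' @param k_range integer vector of candidate K.
#' @return data.frame with columns `K` and `inertia`.
#' @export
elbow_table <- function(X, k_range = 1:5, n_init = 10, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  data.frame(K = k_range,
             inertia = vapply(k_range, function(K)
               kmeans_fit(X, K, n_init = n_init,
                          seed = if (is.null(seed)) NULL else seed + K)$inertia,
               numeric(1)))
}

#' Mean silhouette width of a clustering
#'
#' Average over points of `(b - a) / max(a, b)`, where `a` is the mean
#' within-cluster distance and `b` the mean distance to the nearest other
#' cluster (computed by [cluster::silhouette()]).
#'
#' @param X numeric matrix.
#' @param labels cluster labels (at least 2 distinct values).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(X, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    grf_error("silhouette needs at least 2 clusters", "grf_argument_error")
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(X)))
  mean(sil[, "sil_width"])
}
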