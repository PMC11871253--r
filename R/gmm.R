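# ---- Gaussian mixture model fitted by EM, with BIC model selection ----
#
# The mixture density is p(x) = sum_k pi_k N(x | mu_k, Sigma_k). EM alternates
# an E-step (posterior responsibilities of each component for each point) and
# an M-step (weighted ML updates of weights, means and covariances), starting
# from k-means++-seeded hard assignments, with multiple restarts.

logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

# log N(x | mu, Sigma) for every row of X, one column per component
gmm_log_dens <- function(X, means, covariances) {
  n <- nrow(X); d <- ncol(X); K <- nrow(means)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2, means[k, ], "-")
    S <- covariances[[k]]
    if (d == 1) {
      logdet <- log(S[1, 1])
      quad <- Xc[, 1]^2 / S[1, 1]
    } else if (all(S[upper.tri(S)] == 0) && all(S[lower.tri(S)] == 0)) {
      v <- diag(S)
      logdet <- sum(log(v))
      quad <- rowSums(sweep(Xc^2, 2, v, "/"))
    } else {
      R <- chol(S)
      logdet <- 2 * sum(log(diag(R)))
      z <- backsolve(R, t(Xc), transpose = TRUE)
      quad <- colSums(z^2)
    }
    L[, k] <- -0.5 * (d * log(2 * pi) + logdet + quad)
  }
  L
}

# E-step: responsibilities and total log-likelihood
gmm_estep <- function(X, weights, means, covariances) {
  L <- sweep(gmm_log_dens(X, means, covariances), 2, log(weights), "+")
  lse <- logsumexp_rows(L)
  list(resp = exp(L - lse), loglik = sum(lse))
}

# M-step: weighted ML parameter updates with a variance floor.
# diag: per-dimension variances floored at var_floor (pmax);
# full/tied: var_floor * I added to the weighted scatter, which bounds all
# eigenvalues below by var_floor (a pmax on the diagonal alone would not
# guarantee positive definiteness).
gmm_mstep <- function(X, resp, covariance_type, var_floor) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  Nk <- colSums(resp)
  if (any(Nk < 1e-10))
    grf_error("a mixture component collapsed to zero weight",
              "grf_degenerate_fit_error")
  weights <- Nk / n
  means <- t(resp) %*% X / Nk
  covariances <- vector("list", K)
  if (covariance_type == "tied") {
    S <- matrix(0, d, d)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ], "-")
      S <- S + crossprod(Xc * resp[, k], Xc)
    }
    S <- S / n + diag(var_floor, d)
    for (k in seq_len(K)) covariances[[k]] <- S
  } else {
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ], "-")
      if (covariance_type == "diag") {
        v <- pmax(colSums(resp[, k] * Xc^2) / Nk[k], var_floor)
        covariances[[k]] <- diag(v, d)
      } else {
        covariances[[k]] <- crossprod(Xc * resp[, k], Xc) / Nk[k] +
          diag(var_floor, d)
      }
    }
  }
  list(weights = weights, means = means, covariances = covariances)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (K == 1) return(centers)
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (k in 2:K) {
    i <- if (sum(d2) > 0) sample.int(n, 1, prob = d2 / sum(d2))
         else sample.int(n, 1)
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ], "-")^2))
  }
  centers
}

n_gmm_params <- function(K, d, covariance_type) {
  cov_p <- switch(covariance_type,
                  full = K * d * (d + 1) / 2,
                  diag = K * d,
                  tied = d * (d + 1) / 2)
  (K - 1) + K * d + cov_p
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Runs EM from `n_init` k-means++-seeded starts and keeps the run with the
#' best final log-likelihood. The log-likelihood is checked to be
#' non-decreasing across iterations (tolerance 1e-8). Covariances are kept
#' positive-definite by a variance floor.
#'
#' @param X numeric matrix (n x d) of feature vectors, n >= K.
#' @param K number of mixture components (>= 1).
#' @param covariance_type `"diag"` (default; with a handful of subjects in six
#'   dimensions a full covariance is barely identifiable), `"full"`, or
#'   `"tied"` (one full covariance shared by all components).
#' @param n_init number of random restarts (default 10).
#' @param seed integer seed for reproducible initialization, or `NULL` to use
#'   the current RNG state.
#' @param tol convergence tolerance on the change in mean log-likelihood per
#'   point (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500); reaching
#'   it returns `converged = FALSE` rather than an error.
#' @param var_floor variance floor (default 1e-4).
#' @return an object of class `grf_gmm`: `K`, `weights`, `means` (K x d),
#'   `covariances` (list of d x d matrices), `covariance_type`,
#'   `log_likelihood`, `n_params`, `converged`, `n_iter`, `var_floor`.
#' @export
gmm_fit <- function(X, K, covariance_type = c("diag", "full", "tied"),
                    n_init = 10, seed = NULL, tol = 1e-6, max_iter = 500,
                    var_floor = 1e-4) {
  covariance_type <- match.arg(covariance_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (K < 1 || n < K)
    grf_error("need n >= K >= 1", "grf_argument_error")
  if (any(!is.finite(X)))
    grf_error("X must be finite", "grf_data_error")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      fit <- tryCatch(
        gmm_em_once(X, K, covariance_type, tol, max_iter, var_floor),
        grf_degenerate_fit_error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$log_likelihood > best$log_likelihood))
        best <- fit
    }
  })
  if (is.null(best))
    grf_error("all EM restarts collapsed; data may be degenerate for this K",
              "grf_degenerate_fit_error")
  best$n_params <- n_gmm_params(K, d, covariance_type)
  class(best) <- "grf_gmm"
  best
}

# one EM run from a fresh k-means++ start; consumes the current RNG stream
gmm_em_once <- function(X, K, covariance_type, tol, max_iter, var_floor) {
  n <- nrow(X)
  centers <- kmeanspp_centers(X, K)
  # hard-assign to nearest seed center to form initial responsibilities
  d2 <- vapply(seq_len(K),
               function(k) rowSums(sweep(X, 2, centers[k, ], "-")^2),
               numeric(n))
  lab <- max.col(-d2, ties.method = "first")
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), lab)] <- 1
  par <- gmm_mstep(X, resp, covariance_type, var_floor)
  ll <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    e <- gmm_estep(X, par$weights, par$means, par$covariances)
    if (e$loglik < ll - 1e-8)
      grf_error("EM log-likelihood decreased", "grf_internal_error")
    if (is.finite(ll) && (e$loglik - ll) / nrow(X) < tol) {
      ll <- e$loglik
      converged <- TRUE
      break
    }
    ll <- e$loglik
    par <- gmm_mstep(X, e$resp, covariance_type, var_floor)
  }
  list(K = K, weights = par$weights, means = par$means,
       covariances = par$covariances, covariance_type = covariance_type,
       log_likelihood = ll, converged = converged, n_iter = iter,
       var_floor = var_floor)
}

#' @export
print.grf_gmm <- function(x, ...) {
  cat(sprintf("<grf_gmm> K=%d, %s covariance, logL=%.4f, %s in %d iterations\n",
              x$K, x$covariance_type, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  weights:", sprintf("%.3f", x$weights), "\n")
  invisible(x)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = -2 logL + p ln(n)` where the parameter count `p` is
#' `(K-1) + K d` plus `K d(d+1)/2` (full), `K d` (diag) or `d(d+1)/2` (tied).
#' Lower is better.
#'
#' @param model a `grf_gmm` from [gmm_fit()].
#' @param X the data the model was fitted on (n enters the penalty).
#' @return the BIC value.
#' @export
gmm_bic <- function(model, X) {
  stopifnot(inherits(model, "grf_gmm"))
  -2 * model$log_likelihood + model$n_params * log(nrow(as.matrix(X)))
}

#' Select the number of mixture components by BIC
#'
#' Fits a mixture for every K in `k_range` and returns the K minimizing BIC,
#' with ties broken toward the smaller K (parsimony). A K whose fit fails is
#' skipped with a warning.
#'
#' @inheritParams gmm_fit
#' @param k_range integer vector of candidate K (max <= n).
#' @param ... further arguments passed to [gmm_fit()].
#' @return list with `K` (selected), `table` (data.frame K / log_likelihood /
#'   n_params / bic / converged), and `models` (the fitted `grf_gmm`s, named
#'   by K).
#' @export
select_k <- function(X, k_range = 1:5, covariance_type = "diag",
                     n_init = 10, seed = NULL, ...) {
  X <- as.matrix(X)
  if (max(k_range) > nrow(X))
    grf_error("max(k_range) exceeds the number of points",
              "grf_argument_error")
  k_range <- sort(unique(as.integer(k_range)))
  rows <- list(); models <- list()
  for (K in k_range) {
    fit <- tryCatch(
      gmm_fit(X, K, covariance_type = covariance_type, n_init = n_init,
              seed = if (is.null(seed)) NULL else seed + K, ...),
      error = function(e) {
        warning(sprintf("K = %d skipped: %s", K, conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    models[[as.character(K)]] <- fit
    rows[[length(rows) + 1]] <-
      data.frame(K = K, log_likelihood = fit$log_likelihood,
                 n_params = fit$n_params, bic = gmm_bic(fit, X),
                 converged = fit$converged)
  }
  if (!length(rows))
    grf_error("no K in k_range could be fitted", "grf_degenerate_fit_error")
  tab <- do.call(rbind, rows)
  list(K = tab$K[which.min(tab$bic)], table = tab, models = models)
}

#' Posterior assignment of points to mixture components
#'
#' Responsibilities are proportional to `pi_k N(x | mu_k, Sigma_k)` and
#' normalized per row; hard labels are the arg-max responsibility, with ties
#' broken toward the lowest component index.
#'
#' @param model a `grf_gmm`.
#' @param X matrix of points with the model's dimension.
#' @return an object of class `grf_clusters`: integer `labels`,
#'   `responsibilities` (n x K, rows sum to 1), `K`, and (until
#'   [canonicalize_groups()] is applied) `canonical_names = NULL`.
#' @export
gmm_assign <- function(model, X) {
  stopifnot(inherits(model, "grf_gmm"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$means))
    grf_error("X dimension does not match the model", "grf_argument_error")
  e <- gmm_estep(X, model$weights, model$means, model$covariances)
  structure(list(labels = max.col(e$resp, ties.method = "first"),
                 responsibilities = e$resp, K = model$K,
                 canonical_names = NULL, group = NULL),
            class = "grf_clusters")
}
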