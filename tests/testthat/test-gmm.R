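test_that("K = 1 reduces to sample mean and (floored) ML covariance", {
  set.seed(21)
  X <- matrix(stats::rnorm(40 * 3, sd = 2), 40, 3)
  fit <- gmm_fit(X, 1, covariance_type = "full", seed = 1, var_floor = 1e-4)
  expect_equal(fit$weights, 1)
  expect_equal(as.numeric(fit$means), colMeans(X), tolerance = 1e-12)
  S_ml <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(fit$covariances[[1]], S_ml + diag(1e-4, 3), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("a well-separated 1-D mixture is recovered", {
  set.seed(22)
  x <- matrix(c(stats::rnorm(50, 0, 0.1), stats::rnorm(50, 10, 0.1)), ncol = 1)
  fit <- gmm_fit(x, 2, covariance_type = "diag", seed = 3)
  mu <- sort(fit$means[, 1])
  expect_lt(abs(mu[1] - 0), 0.1)
  expect_lt(abs(mu[2] - 10), 0.1)
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
})

test_that("log-likelihood is additive over duplicated data", {
  set.seed(23)
  X <- matrix(stats::rnorm(30 * 2), 30, 2)
  X[16:30, ] <- X[16:30, ] + 4
  fit <- gmm_fit(X, 2, covariance_type = "diag", seed = 5)
  # evaluating the same parameters on the doubled dataset doubles the total
  e2 <- grfclust:::gmm_estep(rbind(X, X), fit$weights, fit$means,
                             fit$covariances)
  expect_equal(e2$loglik, 2 * fit$log_likelihood, tolerance = 1e-9)
  # refitting the doubled data lands on the same solution
  fit2 <- gmm_fit(rbind(X, X), 2, covariance_type = "diag", seed = 5)
  ord1 <- order(fit$means[, 1]); ord2 <- order(fit2$means[, 1])
  expect_equal(fit2$means[ord2, ], fit$means[ord1, ], tolerance = 1e-3)
  expect_equal(fit2$weights[ord2], fit$weights[ord1], tolerance = 1e-3)
  expect_error(gmm_fit(X, 31), class = "grf_argument_error")
})

test_that("parameter counts and BIC follow the stated formula", {
  set.seed(24)
  X <- matrix(stats::rnorm(60 * 6), 60, 6)
  f_full <- gmm_fit(X, 2, covariance_type = "full", seed = 1, n_init = 2)
  f_diag <- gmm_fit(X, 2, covariance_type = "diag", seed = 1, n_init = 2)
  f_tied <- gmm_fit(X, 2, covariance_type = "tied", seed = 1, n_init = 2)
  expect_equal(f_full$n_params, 1 + 12 + 42)  # 55
  expect_equal(f_diag$n_params, 1 + 12 + 12)  # 25
  expect_equal(f_tied$n_params, 1 + 12 + 21)  # 34
  expect_equal(gmm_bic(f_diag, X),
               -2 * f_diag$log_likelihood + 25 * log(60))
  # duplication changes BIC only through n and the log-likelihood
  e2 <- grfclust:::gmm_estep(rbind(X, X), f_diag$weights, f_diag$means,
                             f_diag$covariances)
  m2 <- f_diag
  m2$log_likelihood <- e2$loglik
  expect_equal(gmm_bic(m2, rbind(X, X)),
               -2 * e2$loglik + 25 * log(120))
})

test_that("single EM iterations match a textbook brute-force transcription", {
  set.seed(25)
  for (i in 1:8) {
    n <- sample(10:30, 1)
    d <- sample(1:3, 1)
    K <- sample(1:3, 1)
    X <- matrix(stats::rnorm(n * d), n, d) +
      matrix(rep(stats::rnorm(K, sd = 3), length.out = n), n, d)
    w <- rep(1 / K, K)
    mu <- X[sample.int(n, K), , drop = FALSE]
    covs <- rep(list(diag(1, d)), K)
    for (type in c("full", "diag")) {
      ref <- oracle_em_step(X, w, mu, covs, type = type)
      e <- grfclust:::gmm_estep(X, w, mu, covs)
      expect_equal(e$resp, ref$resp, tolerance = 1e-10)
      expect_equal(e$loglik, ref$loglik, tolerance = 1e-10)
      m <- grfclust:::gmm_mstep(X, e$resp, type, var_floor = 0)
      expect_equal(m$weights, ref$weights, tolerance = 1e-10)
      expect_equal(unname(m$means), unname(ref$means), tolerance = 1e-10)
      for (k in seq_len(K))
        expect_equal(m$covariances[[k]], ref$covs[[k]], tolerance = 1e-10)
    }
  }
})

test_that("fitted log-likelihood matches an established reference", {
  skip_if_not_installed("mclust")
  set.seed(26)
  X <- matrix(stats::rnorm(50 * 3), 50, 3)
  X[26:50, ] <- X[26:50, ] + 3
  fit <- gmm_fit(X, 2, covariance_type = "full", seed = 2, var_floor = 1e-8)
  dens <- vapply(1:2, function(k)
    fit$weights[k] * mclust::dmvnorm(X, fit$means[k, ],
                                     fit$covariances[[k]]),
    numeric(nrow(X)))
  expect_equal(sum(log(rowSums(dens))), fit$log_likelihood,
               tolerance = 1e-4)
})

test_that("BIC model selection finds the true component count", {
  set.seed(27)
  # two well-separated 6-D blobs (inter-mean distance 10 SDs)
  X <- matrix(stats::rnorm(60 * 6, sd = 1), 60, 6)
  X[31:60, ] <- X[31:60, ] + 10 / sqrt(6)
  sel <- select_k(X, 1:5, covariance_type = "diag", seed = 1)
  expect_equal(sel$K, 2)
  expect_equal(nrow(sel$table), 5)
  # a single blob selects K = 1
  Y <- matrix(stats::rnorm(60 * 6), 60, 6)
  expect_equal(select_k(Y, 1:5, covariance_type = "diag", seed = 1)$K, 1)
  expect_error(select_k(Y, 1:100), class = "grf_argument_error")
})

test_that("posterior assignment behaves at the model's landmarks", {
  mu <- matrix(c(0, 0, 5, 0), 2, 2, byrow = TRUE)
  model <- structure(list(K = 2, weights = c(0.5, 0.5), means = mu,
                          covariances = rep(list(diag(0.25, 2)), 2),
                          covariance_type = "diag", log_likelihood = 0,
                          n_params = 9, converged = TRUE, n_iter = 1,
                          var_floor = 0), class = "grf_gmm")
  at_mu1 <- gmm_assign(model, matrix(c(0, 0), 1, 2))
  expect_gt(at_mu1$responsibilities[1, 1], 0.99)
  expect_equal(at_mu1$labels, 1L)
  # equidistant point between identical-shape equal-weight components
  mid <- gmm_assign(model, matrix(c(2.5, 0), 1, 2))
  expect_equal(as.numeric(mid$responsibilities), c(0.5, 0.5),
               tolerance = 1e-9)
  expect_equal(mid$labels, 1L)  # tie to the lowest component index
  # K = 1: responsibilities exactly 1
  m1 <- model
  m1$K <- 1L; m1$weights <- 1; m1$means <- mu[1, , drop = FALSE]
  m1$covariances <- m1$covariances[1]
  a1 <- gmm_assign(m1, matrix(stats::rnorm(10), 5, 2))
  expect_true(all(a1$responsibilities == 1))
  # rows always sum to 1
  set.seed(28)
  a <- gmm_assign(model, matrix(stats::rnorm(40), 20, 2))
  expect_equal(rowSums(a$responsibilities), rep(1, 20), tolerance = 1e-9)
  expect_equal(a$labels, max.col(a$responsibilities, ties.method = "first"))
})

test_that("mixtures with swapped components canonicalize identically", {
  set.seed(29)
  X <- matrix(stats::rnorm(40 * 2), 40, 2)
  X[1:25, ] <- X[1:25, ] + 6
  fit <- gmm_fit(X, 2, seed = 4)
  swapped <- fit
  swapped$weights <- rev(fit$weights)
  swapped$means <- fit$means[2:1, ]
  swapped$covariances <- fit$covariances[2:1]
  r1 <- canonicalize_groups(gmm_assign(fit, X), r_ml = X[, 1])
  r2 <- canonicalize_groups(gmm_assign(swapped, X), r_ml = X[, 1])
  expect_equal(r1$group, r2$group)
})
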