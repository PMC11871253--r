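# Independent brute-force oracles: literal transcriptions of the defining
# formulas, kept free of any package internals they are used to check.

oracle_pearson <- function(h, p) {
  n <- length(h)
  hb <- sum(h) / n
  pb <- sum(p) / n
  num <- 0; dh <- 0; dp <- 0
  for (i in seq_len(n)) {
    num <- num + (h[i] - hb) * (p[i] - pb)
    dh <- dh + (h[i] - hb)^2
    dp <- dp + (p[i] - pb)^2
  }
  num / sqrt(dh * dp)
}

oracle_smape <- function(h, p) {
  n <- length(h)
  s <- 0
  for (i in seq_len(n)) {
    den <- (abs(h[i]) + abs(p[i])) / 2
    if (den > 0) s <- s + abs(h[i] - p[i]) / den
  }
  s / n
}

# longest contiguous run of TRUE with length >= min_len, earliest on ties;
# returns c(start, end_exclusive) or NULL
oracle_longest_run <- function(above, min_len) {
  n <- length(above)
  best <- NULL; best_len <- 0
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      len <- j - i + 1
      if (len >= min_len && len > best_len) {
        best <- c(i, j + 1); best_len <- len
      }
      i <- j + 1
    } else i <- i + 1
  }
  best
}

# one textbook EM iteration (E then M) with explicit loops
oracle_em_step <- function(X, weights, means, covs, type = "full") {
  n <- nrow(X); d <- ncol(X); K <- length(weights)
  dens <- matrix(0, n, K)
  for (k in seq_len(K)) {
    S <- covs[[k]]
    Si <- solve(S)
    nc <- 1 / sqrt((2 * pi)^d * det(S))
    for (i in seq_len(n)) {
      xc <- X[i, ] - means[k, ]
      dens[i, k] <- weights[k] * nc * exp(-0.5 * c(t(xc) %*% Si %*% xc))
    }
  }
  loglik <- sum(log(rowSums(dens)))
  resp <- dens / rowSums(dens)
  Nk <- colSums(resp)
  w2 <- Nk / n
  mu2 <- matrix(0, K, d)
  S2 <- vector("list", K)
  for (k in seq_len(K)) {
    for (j in seq_len(d)) mu2[k, j] <- sum(resp[, k] * X[, j]) / Nk[k]
    M <- matrix(0, d, d)
    for (i in seq_len(n)) {
      xc <- X[i, ] - mu2[k, ]
      M <- M + resp[i, k] * outer(xc, xc)
    }
    S2[[k]] <- M / Nk[k]
    if (type == "diag") S2[[k]] <- diag(diag(S2[[k]]), d)
  }
  list(resp = resp, loglik = loglik, weights = w2, means = mu2, covs = S2)
}
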