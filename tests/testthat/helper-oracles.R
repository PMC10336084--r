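# Independent brute-force oracles used across the test files. These are
# deliberately written from first principles (explicit rank construction,
# explicit covariance sums, dense matrix algebra) so they share no code
# path with the package implementation they check.

# average ranks computed by scanning sorted positions, no call to rank()
brute_ranks <- function(v) {
  n <- length(v)
  ord <- order(v)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Pearson correlation via raw sums
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

brute_spearman <- function(x, y) {
  brute_pearson(brute_ranks(x), brute_ranks(y))
}

# BH step-up from the definition: q(i) = min_{j >= rank(i)} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# dense evaluation of the marginal Gaussian log-density at a fit's
# estimates: y ~ N(X beta, sigma2 I + sigma2_b Zs Zs' + sum_k (sigma2 /
# lambda_k) Zk Zk')
dense_marginal_loglik <- function(fit, y, X_full, subject = NULL,
                                  Z_smooth = NULL) {
  n <- length(y)
  V <- diag(n) * fit$sigma2
  if (!is.null(subject)) {
    Zs <- stats::model.matrix(~ 0 + factor(subject))
    V <- V + fit$sigma2_b * tcrossprod(Zs)
  }
  if (!is.null(Z_smooth) && ncol(Z_smooth)) {
    g <- rep(fit$sigma2 / fit$lambda, times = fit$smooth_cols)
    V <- V + Z_smooth %*% diag(g, length(g)) %*% t(Z_smooth)
  }
  r <- drop(y - X_full %*% fit$beta)
  cV <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cV))) +
            sum(backsolve(cV, r, transpose = TRUE)^2))
}

# small symmetric zero-diagonal matrix with reproducible weights
toy_symmetric <- function(n, seed = 1, density = 1, nonneg = TRUE) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  v <- if (nonneg) stats::rlnorm(sum(ut)) else stats::runif(sum(ut), -1, 1)
  v[stats::runif(sum(ut)) > density] <- 0
  m[ut] <- v
  m + t(m)
}

# minimal fake gamm_fit for exercising select_model()'s decision logic
fake_fit <- function(id, loglik, n_fixed, aic = NULL, n = 100,
                     converged = TRUE) {
  structure(list(model_id = id, loglik = loglik, n_fixed = n_fixed,
                 n_varpar = 2,
                 aic = if (is.null(aic)) -2 * loglik + 2 * (n_fixed + 2)
                       else aic,
                 n = n, y_fingerprint = c(n, 0, 1),
                 converged = converged),
            class = "gamm_fit")
}

# small cohort for trajectory tests without the connectome stage
toy_cohort <- function(n_subj = 60, waves = 2, seed = 42) {
  cfg <- sim_config(n_adhd = ceiling(n_subj / 2),
                    n_control = floor(n_subj / 2),
                    n_nodes = 60, waves = waves, retention = 1,
                    seed = seed)
  simulate_cohort(cfg)
}
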