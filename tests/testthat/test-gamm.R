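test_that("balanced random-intercept ML matches the closed forms", {
  set.seed(51)
  ns <- 100; m <- 2
  subj <- rep(seq_len(ns), each = m)
  y <- 2 + rnorm(ns, 0, 1)[subj] + rnorm(ns * m, 0, 0.5)
  fit <- fit_gamm(y, matrix(1, ns * m, 1), subject = subj)
  # closed-form ML for the balanced one-way layout
  ybar_i <- tapply(y, subj, mean)
  ybar <- mean(y)
  s2e <- sum((y - ybar_i[subj])^2) / (ns * (m - 1))
  tau <- m * sum((ybar_i - ybar)^2) / ns        # = s2e + m s2b at the MLE
  s2b <- max((tau - s2e) / m, 0)
  expect_equal(unname(fit$beta[1]), ybar, tolerance = 1e-9)
  expect_equal(fit$sigma2, s2e, tolerance = 1e-6)
  expect_equal(fit$sigma2_b, s2b, tolerance = 1e-6)
  # and the reported likelihood is the marginal density at those estimates
  ll <- dense_marginal_loglik(fit, y, matrix(1, ns * m, 1), subj)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("reported ML log-likelihood equals dense marginal evaluation", {
  set.seed(53)
  for (rep in 1:3) {
    n <- sample(150:350, 1)
    subj <- sample(seq_len(60), n, replace = TRUE)
    age <- runif(n, 9, 14)
    X <- cbind(intercept = 1, z = rnorm(n), w = rbinom(n, 1, 0.4))
    basis <- spline_basis(age, k = 4)
    y <- 0.3 + 0.1 * X[, "z"] + 0.05 * (age - 11)^2 / 4 +
      rnorm(60, 0, 0.15)[subj] + rnorm(n, 0, 0.1)
    # intercept-only random effect
    f0 <- fit_gamm(y, X, subject = subj)
    expect_equal(f0$loglik, dense_marginal_loglik(f0, y, X, subj),
                 tolerance = 1e-6)
    # one smooth
    f1 <- fit_gamm(y, X, subject = subj, smooths = list(basis))
    expect_equal(
      f1$loglik,
      dense_marginal_loglik(f1, y, cbind(X, basis$X), subj, basis$Z),
      tolerance = 1e-6)
    # two smooths (group-deviation layout)
    g <- rbinom(n, 1, 0.5)
    sm2 <- list(X = basis$X * g, Z = basis$Z * g)
    f2 <- fit_gamm(y, cbind(X, grp = g), subject = subj,
                   smooths = list(basis, sm2))
    expect_equal(
      f2$loglik,
      dense_marginal_loglik(f2, y, cbind(X, g, basis$X, sm2$X), subj,
                            cbind(basis$Z, sm2$Z)),
      tolerance = 1e-6)
    # smooth-only model, no subject intercept
    f3 <- fit_gamm(y, X, smooths = list(basis))
    expect_equal(
      f3$loglik,
      dense_marginal_loglik(f3, y, cbind(X, basis$X), NULL, basis$Z),
      tolerance = 1e-6)
  }
})

test_that("singular fixed designs error with the offending column", {
  set.seed(55)
  n <- 60
  X <- cbind(intercept = 1, a = rnorm(n), zero = 0)
  expect_error(fit_gamm(rnorm(n), X, subject = rep(1:30, 2)),
               "singular.*zero")
  X2 <- cbind(intercept = 1, a = rnorm(n))
  X2 <- cbind(X2, dup = X2[, "a"])
  expect_error(fit_gamm(rnorm(n), X2, subject = rep(1:30, 2)),
               "singular")
  expect_error(fit_gamm(c(rnorm(n - 1), NA), X2[, 1:2],
                        subject = rep(1:30, 2)), "missing")
})

test_that("log-likelihood is monotone along the nested ladder", {
  set.seed(57)
  co <- toy_cohort(n_subj = 50, waves = 3, seed = 9)
  scen <- list(scenario("group_by_age", 0.3, slope_adhd = 0.05),
               scenario("null", 0.3), scenario("increasing", 0.2,
                                               slope_control = 0.04))
  tab <- simulate_coupling_table(co, scen, noise_sd = 0.08, seed = 58)
  for (r in 1:3) {
    d <- tab[tab$region == r, ]
    X <- cbind(intercept = 1, fd = d$fd_fmri)
    adhd <- as.numeric(d$group == "adhd")
    basis <- spline_basis(d$age, 4)
    m0 <- fit_gamm(d$rho, X, d$subject_id, model_id = "M0")
    m1 <- fit_gamm(d$rho, X, d$subject_id, list(basis), model_id = "M1")
    m2 <- fit_gamm(d$rho, cbind(X, adhd), d$subject_id, list(basis),
                   model_id = "M2")
    m3 <- fit_gamm(d$rho, cbind(X, adhd), d$subject_id,
                   list(basis, list(X = basis$X * adhd,
                                    Z = basis$Z * adhd)), model_id = "M3")
    lls <- c(m0$loglik, m1$loglik, m2$loglik, m3$loglik)
    expect_true(all(diff(lls) >= -1e-6))
  }
})

test_that("fitted age curves agree with mgcv on the same model", {
  set.seed(59)
  n <- 250
  subj <- sample(1:80, n, replace = TRUE)
  age <- runif(n, 9, 14)
  y <- 0.2 + 0.1 * sin((age - 9) / 2) + rnorm(80, 0, 0.1)[subj] +
    rnorm(n, 0, 0.08)
  basis <- spline_basis(age, 4)
  ours <- fit_gamm(y, matrix(1, n, 1), subject = subj,
                   smooths = list(basis))
  d <- data.frame(y = y, age = age, subj = factor(subj))
  mg <- mgcv::gam(y ~ s(age, k = 4) + s(subj, bs = "re"), data = d,
                  method = "ML")
  expect_gt(cor(ours$fitted, fitted(mg)), 0.99)
  grid <- seq(9.2, 13.8, length.out = 30)
  pr <- predict(basis, grid)
  ours_curve <- drop(pr$X %*% ours$beta[2]) +
    drop(pr$Z %*% ours$u_smooth)
  mg_curve <- predict(mg, newdata = data.frame(age = grid,
                                               subj = d$subj[1]),
                      type = "terms")[, "s(age)"]
  expect_gt(cor(ours_curve, mg_curve), 0.98)
})
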