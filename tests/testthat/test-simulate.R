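test_that("cohort simulation is deterministic and respects the design", {
  cfg <- sim_config(seed = 101, n_nodes = 60)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  cfg2 <- sim_config(seed = 102, n_nodes = 60)
  expect_false(identical(co1, simulate_cohort(cfg2)))

  # full retention: every subject attends every wave
  cfg_full <- sim_config(retention = 1, seed = 103, n_nodes = 60)
  co_full <- simulate_cohort(cfg_full)
  expect_equal(nrow(co_full), 175 * 3)

  # structure: groups, scanner flag, medication in ADHD only
  expect_equal(sum(!duplicated(co1$subject_id)), 175)
  expect_identical(unique(co1$scanner[co1$wave == 3]),
                   factor("post_upgrade",
                          levels = c("pre_upgrade", "post_upgrade")))
  expect_true(all(!co1$medicated[co1$group == "control"]))
  # ages increase across waves within subject
  ord <- order(co1$subject_id, co1$wave)
  by_sub <- split(co1$age[ord], co1$subject_id[ord])
  expect_true(all(vapply(by_sub, function(a) all(diff(a) > 0), logical(1))))
})

test_that("total scan count matches the truncated-binomial expectation", {
  cfg <- sim_config(seed = 105, n_nodes = 60)
  r <- cfg$retention
  # attendance is Bernoulli(r) per wave conditioned on >= 1 attended wave
  expected <- 175 * sum(r) / (1 - prod(1 - r))
  totals <- vapply(1:150, function(i) {
    nrow(simulate_cohort(sim_config(seed = 1000 + i, n_nodes = 60)))
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
  # and the expectation itself sits near the study's 278 scans
  expect_lt(abs(expected - 278), 10)
})

test_that("base topology hits the requested density and is connected", {
  b <- make_base_topology(360, density = 0.25, n_communities = 6, seed = 7)
  ut <- upper.tri(b$weights)
  dens <- mean(b$weights[ut] > 0)
  expect_lt(abs(dens - 0.25), 0.02)
  expect_true(all(b$weights >= 0))
  expect_identical(diag(b$weights), rep(0, 360))
  b2 <- make_base_topology(360, density = 0.25, n_communities = 6, seed = 7)
  expect_identical(b$weights, b2$weights)
  expect_error(make_base_topology(50, density = 1.2), "density")
})

test_that("per-scan SC noise behaves as specified", {
  base <- make_base_topology(60, density = 0.3, n_communities = 3, seed = 9)
  # degenerate noise reproduces the base exactly
  s0 <- simulate_sc(base, subject_sigma = 0, dropout = 0, seed = 1)
  expect_identical(s0$weights, base$weights)

  # dropout zeroes a binomial fraction of present edges
  n_edges <- sum(base$weights[upper.tri(base$weights)] > 0)
  set.seed(11)
  zeroed <- vapply(1:40, function(i) {
    s <- simulate_sc(base, 0, dropout = 0.1)
    n_edges - sum(s$weights[upper.tri(s$weights)] > 0)
  }, numeric(1))
  expect_lt(abs(mean(zeroed) - 0.1 * n_edges),
            4 * sqrt(n_edges * 0.1 * 0.9 / 40))

  # per-edge CV increases monotonically with subject_sigma
  cv_at <- function(sig) {
    set.seed(13)
    scans <- lapply(1:50, function(i) simulate_sc(base, sig, 0))
    cv <- edge_cv(scans)
    mean(cv[upper.tri(cv)][is.finite(cv[upper.tri(cv)])])
  }
  cvs <- vapply(c(0.1, 0.3, 0.6), cv_at, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("scenario targets follow their piecewise-linear definitions", {
  s_null <- scenario("null", base_rho = 0.3)
  expect_equal(target_coupling(s_null, "adhd", 12.7), 0.3)
  s_inc <- scenario("increasing", 0.2, slope_control = 0.04)
  expect_equal(target_coupling(s_inc, "control", 14), 0.4)
  s_pl <- scenario("increase_then_plateau", 0.2, slope_control = 0.04,
                   plateau_age = 12)
  expect_equal(target_coupling(s_pl, "control", 13),
               target_coupling(s_pl, "control", 12))
  s_off <- scenario("group_offset", 0.3, offset_adhd = -0.1)
  expect_equal(target_coupling(s_off, "adhd", 10) -
                 target_coupling(s_off, "control", 10), -0.1)
  s_ga <- scenario("group_by_age", 0.3, slope_adhd = 0.05)
  expect_equal(target_coupling(s_ga, "control", 13), 0.3)
  expect_equal(target_coupling(s_ga, "adhd", 13), 0.5)
  # clipped to the valid coupling range
  s_big <- scenario("increasing", 0.9, slope_control = 0.1)
  expect_equal(target_coupling(s_big, "control", 14), 0.95)
  s_bad <- s_null; s_bad$kind <- "quadratic"
  expect_error(target_coupling(s_bad, "control", 10), "quadratic")
})

test_that("copula calibration matches the closed form", {
  expect_equal(calibrate_copula(0), 0)
  expect_equal(calibrate_copula(0.5), 2 * sin(pi / 12))
  expect_equal(calibrate_copula(0.5), 0.5176381, tolerance = 1e-6)
  expect_gt(calibrate_copula(1 - 1e-9), 1 - 1e-6)
  expect_equal(calibrate_copula(-0.5), -calibrate_copula(0.5))
  expect_error(calibrate_copula(1), "< 1")
})

test_that("planted coupling is recovered from generated connectome pairs", {
  base <- make_base_topology(120, density = 0.25, n_communities = 6,
                             seed = 15)
  # strong targets, shared high coupling: measured close to 1
  set.seed(17)
  sch <- simulate_sc(base, 0.3, 0.05)
  fch <- simulate_fc_given_sc(sch, rep(0.99, 120))
  ph <- regional_coupling(sch, fch)
  expect_gt(mean(ph$rho, na.rm = TRUE), 0.9)

  # null targets: measured couplings center on zero
  sc0 <- simulate_sc(base, 0.3, 0.05)
  fc0 <- simulate_fc_given_sc(sc0, rep(0, 120))
  p0 <- regional_coupling(sc0, fc0)
  expect_lt(abs(mean(p0$rho, na.rm = TRUE)), 0.05)

  # rank recovery across nodes for targets spanning 0.1-0.6
  tgt <- seq(0.1, 0.6, length.out = 120)
  meas <- matrix(NA_real_, 15, 120)
  for (s in 1:15) {
    sc <- simulate_sc(base, 0.3, 0.05)
    fc <- simulate_fc_given_sc(sc, pmin(pmax(2 * tgt - mean(tgt), -0.95),
                                        0.95))
    meas[s, ] <- regional_coupling(sc, fc)$rho
  }
  expect_gt(cor(tgt, colMeans(meas), method = "spearman"), 0.9)
})

test_that("expected measured coupling increases with the planted target", {
  base <- make_base_topology(50, density = 0.4, n_communities = 2, seed = 19)
  set.seed(21)
  grid <- c(0.1, 0.3, 0.5, 0.7)
  means <- vapply(grid, function(t) {
    mean(vapply(1:25, function(i) {
      sc <- simulate_sc(base, 0.3, 0)
      fc <- simulate_fc_given_sc(sc, rep(t, 50))
      mean(regional_coupling(sc, fc)$rho, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("full study generation is deterministic with scenario separation", {
  map <- c(replicate(15, scenario("increasing", 0.25, slope_control = 0.06),
                     simplify = FALSE),
           replicate(45, scenario("null", 0.25), simplify = FALSE))
  cfg <- sim_config(n_adhd = 20, n_control = 20, n_nodes = 60,
                    retention = 1, scenario_map = map, seed = 301)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$cohort, st2$cohort)
  expect_identical(st1$fc[[5]]$weights, st2$fc[[5]]$weights)

  # generated matrices satisfy the connectome invariants
  expect_true(all(st1$sc[[1]]$weights >= 0))
  expect_true(all(abs(st1$fc[[1]]$weights) <= 1))
  expect_identical(st1$fc[[2]]$weights, t(st1$fc[[2]]$weights))

  # wave-3 minus wave-1 coupling is positive for increasing nodes, ~0 null
  tab <- coupling_dataset(st1$cohort, st1$sc, st1$fc)
  w1 <- tapply(tab$rho[tab$wave == 1], tab$region[tab$wave == 1],
               mean, na.rm = TRUE)
  w3 <- tapply(tab$rho[tab$wave == 3], tab$region[tab$wave == 3],
               mean, na.rm = TRUE)
  delta <- w3 - w1
  expect_gt(mean(delta[1:15]), 0.1)
  expect_lt(abs(mean(delta[16:60])), 0.05)
})
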