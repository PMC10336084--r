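test_that("spearman_rho handles monotone, reversed and tied inputs", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  # classic 1 - 6 sum(d^2) / (n (n^2 - 1)) with no ties
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)),
               1 - 6 * 4 / (5 * 24))
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "finite")
})

test_that("spearman_rho matches the brute-force rank oracle with ties", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- sample(round(rnorm(n), sample(0:2, 1)))   # induce ties
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), brute_spearman(x, y),
                 tolerance = 1e-10)
  }
})

test_that("regional coupling selects non-zero structural edges only", {
  # region 1: sc profile (2, 4, 0, 6) over regions 2..5; fc arbitrary
  sc_m <- matrix(0, 5, 5)
  sc_m[1, 2] <- 2; sc_m[1, 3] <- 4; sc_m[1, 5] <- 6
  sc_m[2, 3] <- 1; sc_m[2, 4] <- 3; sc_m[3, 4] <- 2; sc_m[4, 5] <- 1
  sc_m <- sc_m + t(sc_m)
  fc_m <- matrix(0, 5, 5)
  fc_m[1, 2] <- 0.1; fc_m[1, 3] <- 0.2; fc_m[1, 4] <- 0.5; fc_m[1, 5] <- 0.3
  fc_m[2, 3] <- -0.2; fc_m[2, 4] <- 0.4; fc_m[3, 4] <- 0.1
  fc_m[3, 5] <- 0.6; fc_m[4, 5] <- -0.5; fc_m[2, 5] <- 0.2
  fc_m <- fc_m + t(fc_m)
  sc <- connectome(sc_m, "structural")
  fc <- connectome(fc_m, "functional")
  prof <- regional_coupling(sc, fc, min_edges = 3)
  # pairs (2, 0.1), (4, 0.2), (6, 0.3): perfectly monotone
  expect_equal(prof$rho[1], 1.0)
  expect_equal(prof$n_edges_used[1], 3L)
  # region 4 has 3 non-zero edges, region 2 has 3; all defined
  expect_true(all(!is.na(prof$rho[prof$n_edges_used >= 3])))

  # fewer than min_edges non-zero edges -> missing
  sc2 <- sc_m; sc2[1, 5] <- sc2[5, 1] <- 0
  p2 <- regional_coupling(connectome(sc2, "structural"), fc, min_edges = 3)
  expect_true(is.na(p2$rho[1]))
  expect_equal(p2$n_edges_used[1], 2L)

  # excluded nodes are always missing
  p3 <- regional_coupling(sc, fc, excluded = c(1L, 4L))
  expect_true(all(is.na(p3$rho[c(1, 4)])))
})

test_that("coupling is invariant to monotone transforms of SC weights", {
  set.seed(31)
  base <- make_base_topology(30, density = 0.5, n_communities = 3, seed = 2)
  sc <- simulate_sc(base, 0.3, 0.05)
  fc <- simulate_fc_given_sc(sc, rep(0.4, 30))
  p0 <- regional_coupling(sc, fc)
  sc_exp <- sc; sc_exp$weights <- exp(sc$weights) - 1
  sc_exp$weights[sc$weights == 0] <- 0
  p1 <- regional_coupling(sc_exp, fc)
  sc_k <- sc; sc_k$weights <- sc$weights * 1000
  p2 <- regional_coupling(sc_k, fc)
  expect_equal(p0$rho, p1$rho, tolerance = 1e-12)
  expect_equal(p0$rho, p2$rho, tolerance = 1e-12)

  # fc equal to a strictly increasing transform of sc on its support
  fc2 <- sc
  fc2$weights <- tanh(sc$weights / max(sc$weights))
  fc2 <- connectome(fc2$weights, "functional")
  p4 <- regional_coupling(sc, fc2)
  expect_true(all(abs(p4$rho[!is.na(p4$rho)] - 1) < 1e-12))
})

test_that("coupling_dataset builds the long table with exclusions", {
  co <- toy_cohort(n_subj = 4, waves = 1, seed = 17)
  base <- make_base_topology(12, density = 0.6, n_communities = 2, seed = 4)
  sc <- lapply(seq_len(nrow(co)), function(i) simulate_sc(base, 0.3, 0))
  fc <- lapply(sc, function(s) simulate_fc_given_sc(s, rep(0.3, 12)))
  mask <- consistency_mask(edge_cv(sc), 75)
  # force one node out of the mask
  mask$mask[2, ] <- 0L; mask$mask[, 2] <- 0L
  tab <- coupling_dataset(co, sc, fc, mask = mask)
  expect_equal(nrow(tab), nrow(co) * 11)
  expect_false(2 %in% tab$region)
  expect_identical(tab$missing, is.na(tab$rho))

  # round-trip through CSV preserves values
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  tab2 <- utils::read.csv(f)
  expect_equal(tab2$rho, tab$rho, tolerance = 1e-12)

  expect_error(coupling_dataset(co, sc[-1], fc),
               "both matrices")
})
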