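# Synthetic longitudinal cohort generator.
#
# Emulates the statistical structure of a two-group longitudinal
# neuroimaging study (ADHD vs control, up to three waves ~18 months apart,
# ages 9-14, missing waves) with paired structural/functional connectomes
# whose regional coupling follows planted developmental scenarios. Coupling
# is planted at the profile level through a Gaussian copula -- exactly
# controllable, with no biophysical forward model.

#' Define a planted coupling scenario for one region
#'
#' @param kind One of `"increasing"`, `"increase_then_plateau"`,
#'   `"group_offset"`, `"group_by_age"`, `"null"`.
#' @param base_rho Target Spearman coupling at age 9.
#' @param slope_control Per-year change applied to both groups
#'   (`increasing`, `increase_then_plateau`).
#' @param slope_adhd Per-year ADHD-specific change (`group_by_age`).
#' @param plateau_age Age (years) after which the trajectory is flat
#'   (`increase_then_plateau`).
#' @param offset_adhd Additive ADHD group difference (`group_offset`).
#' @return A `scenario` object.
#' @export
scenario <- function(kind = c("null", "increasing", "increase_then_plateau",
                              "group_offset", "group_by_age"),
                     base_rho = 0.25, slope_control = 0, slope_adhd = 0,
                     plateau_age = 12, offset_adhd = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, base_rho = base_rho,
                 slope_control = slope_control, slope_adhd = slope_adhd,
                 plateau_age = plateau_age, offset_adhd = offset_adhd),
            class = "scenario")
}

#' Target coupling value under a scenario
#'
#' Piecewise-linear planted trajectory, clipped to \[-0.95, 0.95\].
#'
#' @param scen A [scenario].
#' @param group `"control"` or `"adhd"`.
#' @param age Age in years.
#' @return Target Spearman coupling.
#' @export
target_coupling <- function(scen, group, age) {
  stopifnot(inherits(scen, "scenario"))
  group <- match.arg(as.character(group), c("control", "adhd"))
  t0 <- age - 9
  val <- switch(scen$kind,
    null = scen$base_rho,
    increasing = scen$base_rho + scen$slope_control * t0,
    increase_then_plateau =
      scen$base_rho + scen$slope_control * (min(age, scen$plateau_age) - 9),
    group_offset =
      scen$base_rho + if (group == "adhd") scen$offset_adhd else 0,
    group_by_age =
      scen$base_rho + if (group == "adhd") scen$slope_adhd * t0 else 0,
    stop(sprintf("unknown scenario kind '%s'", scen$kind))
  )
  pmin(pmax(val, -0.95), 0.95)
}

#' Gaussian-copula calibration of a Spearman target
#'
#' Pearson correlation of a bivariate Gaussian whose population Spearman
#' correlation equals `target_spearman`: `r = 2 sin(pi rho_s / 6)`.
#'
#' @param target_spearman Spearman correlation, |rho| < 1.
#' @return The corresponding Pearson correlation.
#' @export
calibrate_copula <- function(target_spearman) {
  if (any(abs(target_spearman) >= 1))
    stop("|target_spearman| must be < 1")
  2 * sin(pi * target_spearman / 6)
}

#' Default scenario map
#'
#' 20 `increasing` regions, 10 `increase_then_plateau`, 10 `group_offset`,
#' 10 `group_by_age`, remainder `null` -- mirroring the qualitative pattern
#' of a developmental coupling study: diffuse age increases, a sensory
#' plateau, ADHD hypo-coupling offsets and ADHD-specific catch-up slopes.
#' Baseline coupling varies across regions over `base_range` (deterministic
#' golden-ratio scatter), reflecting the regional coupling gradient of real
#' cortex (strong in sensory regions, weak in association cortex).
#'
#' @param n_nodes Number of regions (>= 50).
#' @param base_range Range of region baseline coupling at age 9 (set both
#'   endpoints equal for a constant baseline).
#' @param age_slope Planted age slope (per year) for `increasing` and
#'   `increase_then_plateau` regions.
#' @param plateau_age Plateau onset age.
#' @param offset_adhd ADHD offset for `group_offset` regions (negative:
#'   weaker coupling in ADHD).
#' @param adhd_slope ADHD-specific slope for `group_by_age` regions
#'   (controls flat).
#' @return List of length `n_nodes` of [scenario] objects.
#' @export
default_scenario_map <- function(n_nodes = 360, base_range = c(0.10, 0.40),
                                 age_slope = 0.04, plateau_age = 12,
                                 offset_adhd = -0.10, adhd_slope = 0.05) {
  if (n_nodes < 50) stop("default scenario map needs >= 50 nodes")
  phi <- (sqrt(5) - 1) / 2
  base <- base_range[1] +
    diff(base_range) * ((seq_len(n_nodes) * phi) %% 1)
  map <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    map[[i]] <- if (i <= 20)
      scenario("increasing", base[i], slope_control = age_slope)
    else if (i <= 30)
      scenario("increase_then_plateau", base[i], slope_control = age_slope,
               plateau_age = plateau_age)
    else if (i <= 40)
      scenario("group_offset", base[i], offset_adhd = offset_adhd)
    else if (i <= 50)
      scenario("group_by_age", base[i], slope_adhd = adhd_slope)
    else scenario("null", base[i])
  }
  map
}

#' Simulation configuration
#'
#' Defaults emulate the study sample: 91 ADHD and 84 control subjects, up
#' to three waves ~1.4 years apart starting around age 10.4, ~60% male,
#' per-wave retention tuned so the expected total is about 278 scans with
#' observed per-wave proportions, head-motion distributions matched to the
#' published group/wave means and SDs, scanner upgrade at wave 3, and
#' wave-dependent medication rates in the ADHD group.
#'
#' @param n_adhd,n_control Group sizes.
#' @param n_nodes Number of regions.
#' @param waves Maximum number of waves.
#' @param wave_interval_mean Mean inter-wave interval (years).
#' @param wave_interval_jitter Half-width of the uniform jitter on the
#'   interval (years).
#' @param age_w1_mean,age_w1_sd Wave-1 age distribution (years).
#' @param retention Per-wave attendance probability (scalar or one value
#'   per wave); every subject attends at least one wave.
#' @param prop_male Proportion of male subjects.
#' @param med_prob Per-wave medication probability in the ADHD group.
#' @param fd_dwi_pars,fd_fmri_pars 2 x `waves` x 2 arrays (group x wave x
#'   mean/sd) of frame-wise-displacement gamma-distribution moments (mm);
#'   defaults follow the published per-group, per-wave values.
#' @param scenario_map List of per-region [scenario]s (default
#'   [default_scenario_map()]).
#' @param noise_sd Residual SD of the planted per-scan coupling target.
#' @param subject_sd SD of the subject-by-region random intercept on the
#'   planted target.
#' @param cov_beta Named covariate effects on the planted target
#'   (`fd_dwi`, `fd_fmri`, `scanner`, `sex`, `medicated`).
#' @param density,n_communities Base structural topology parameters.
#' @param subject_sigma Log-scale SD of per-scan edge-weight noise.
#' @param dropout Per-scan fraction of present edges zeroed.
#' @param zero_noise_sd Latent noise SD used for structurally absent edges
#'   in the functional matrix.
#' @param compensate Logical; pre-compensate row targets for the
#'   attenuation introduced by symmetrizing the functional matrix (see the
#'   methods vignette).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_adhd = 91, n_control = 84, n_nodes = 360,
                       waves = 3, wave_interval_mean = 1.4,
                       wave_interval_jitter = 0.15,
                       age_w1_mean = 10.4, age_w1_sd = 0.5,
                       retention = c(0.51, 0.53, 0.30),
                       prop_male = 0.60,
                       med_prob = c(0.21, 0.19, 0.07),
                       fd_dwi_pars = NULL, fd_fmri_pars = NULL,
                       scenario_map = NULL,
                       noise_sd = 0.05, subject_sd = 0.03,
                       cov_beta = c(fd_dwi = 0, fd_fmri = -0.10,
                                    scanner = 0.02, sex = 0, medicated = 0),
                       density = 0.25, n_communities = 6,
                       subject_sigma = 0.3, dropout = 0.05,
                       zero_noise_sd = 0.3, compensate = TRUE,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (n_adhd <= 0 || n_control <= 0 || n_nodes <= 0) stop("counts must be > 0")
  retention <- rep(retention, length.out = waves)
  if (any(retention <= 0) || any(retention > 1))
    stop("retention must lie in (0, 1]")
  med_prob <- rep(med_prob, length.out = waves)
  if (is.null(fd_dwi_pars)) {
    fd_dwi_pars <- array(
      c(0.36, 0.44, 0.38, 0.39, 0.29, 0.33,    # means: control, adhd by wave
        0.11, 0.26, 0.22, 0.14, 0.06, 0.12),   # sds
      dim = c(2, 3, 2),
      dimnames = list(c("control", "adhd"), NULL, c("mean", "sd")))
  }
  if (is.null(fd_fmri_pars)) {
    fd_fmri_pars <- array(
      c(0.14, 0.19, 0.14, 0.15, 0.09, 0.11,
        0.16, 0.16, 0.10, 0.11, 0.05, 0.07),
      dim = c(2, 3, 2),
      dimnames = list(c("control", "adhd"), NULL, c("mean", "sd")))
  }
  if (is.null(scenario_map)) scenario_map <- default_scenario_map(n_nodes)
  if (length(scenario_map) != n_nodes)
    stop("scenario_map length must equal n_nodes")
  structure(list(
    n_adhd = n_adhd, n_control = n_control, n_nodes = n_nodes,
    waves = waves, wave_interval_mean = wave_interval_mean,
    wave_interval_jitter = wave_interval_jitter,
    age_w1_mean = age_w1_mean, age_w1_sd = age_w1_sd,
    retention = retention, prop_male = prop_male, med_prob = med_prob,
    fd_dwi_pars = fd_dwi_pars, fd_fmri_pars = fd_fmri_pars,
    scenario_map = scenario_map, noise_sd = noise_sd,
    subject_sd = subject_sd, cov_beta = cov_beta,
    density = density, n_communities = n_communities,
    subject_sigma = subject_sigma, dropout = dropout,
    zero_noise_sd = zero_noise_sd, compensate = compensate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# gamma draw with given mean/sd, guarding tiny shapes
.rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Simulate a longitudinal cohort table
#'
#' Draws subjects (group, sex), per-wave attendance (Bernoulli retention,
#' redrawn until each subject attends at least one wave), ages (wave-1 age
#' plus jittered intervals), head motion (gamma with group/wave moments),
#' medication (ADHD only, wave-dependent rates) and the scanner flag
#' (post-upgrade at wave 3). Deterministic given the config seed.
#'
#' @param config A [sim_config].
#' @param seed Seed; defaults to `config$seed`. Pass `NA` to use the
#'   current RNG state (used internally by [simulate_study()]).
#' @return Validated cohort data frame, one row per attended scan.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n_sub <- config$n_adhd + config$n_control
  grp <- c(rep("adhd", config$n_adhd), rep("control", config$n_control))
  ids <- sprintf("S%03d", seq_len(n_sub))
  sex <- ifelse(stats::runif(n_sub) < config$prop_male, "male", "female")
  age1 <- stats::rnorm(n_sub, config$age_w1_mean, config$age_w1_sd)
  W <- config$waves
  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    att <- stats::rbinom(W, 1, config$retention)
    while (sum(att) == 0) att <- stats::rbinom(W, 1, config$retention)
    gaps <- config$wave_interval_mean +
      stats::runif(W - 1, -config$wave_interval_jitter,
                   config$wave_interval_jitter)
    ages <- age1[i] + c(0, cumsum(gaps))
    gi <- if (grp[i] == "control") 1L else 2L
    ws <- which(att == 1)
    fd_d <- fd_f <- med <- numeric(length(ws))
    for (k in seq_along(ws)) {
      w <- ws[k]
      fd_d[k] <- .rgamma_ms(1, config$fd_dwi_pars[gi, w, "mean"],
                            config$fd_dwi_pars[gi, w, "sd"])
      fd_f[k] <- .rgamma_ms(1, config$fd_fmri_pars[gi, w, "mean"],
                            config$fd_fmri_pars[gi, w, "sd"])
      med[k] <- if (grp[i] == "adhd")
        stats::rbinom(1, 1, config$med_prob[w]) else 0
    }
    rows[[i]] <- data.frame(
      subject_id = ids[i], group = grp[i], wave = ws,
      age = round(ages[ws], 4), sex = sex[i],
      medicated = med == 1,
      fd_dwi = round(fd_d, 4), fd_fmri = round(fd_f, 4),
      scanner = ifelse(ws == 3, "post_upgrade", "pre_upgrade"),
      stringsAsFactors = FALSE
    )
  }
  validate_cohort(do.call(rbind, rows))
}

#' Simulate a community-structured base structural connectome
#'
#' Stochastic-block topology (within-community edges three times as likely
#' and heavier than between-community edges), log-normal weights, redrawn
#' (bounded retries) until the graph is connected.
#'
#' @param n_nodes Number of regions.
#' @param density Target fraction of non-zero upper-triangle edges.
#' @param n_communities Number of communities.
#' @param seed Optional seed (`NULL`: use current RNG state).
#' @param max_retries Connectivity retry bound.
#' @return A structural [connectome].
#' @export
make_base_topology <- function(n_nodes, density = 0.25, n_communities = 6,
                               seed = NULL, max_retries = 100) {
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  comm <- rep(seq_len(n_communities), length.out = n_nodes)
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  within <- comm[ut[, 1]] == comm[ut[, 2]]
  f_w <- mean(within)
  ratio <- 3
  p_b <- density / (f_w * ratio + (1 - f_w))
  p_w <- min(ratio * p_b, 1)
  p_edge <- ifelse(within, p_w, p_b)
  for (try in seq_len(max_retries)) {
    present <- stats::runif(nrow(ut)) < p_edge
    w <- numeric(nrow(ut))
    w[present] <- stats::rlnorm(sum(present), meanlog = 0, sdlog = 0.6) *
      ifelse(within[present], 1.5, 1)
    W <- matrix(0, n_nodes, n_nodes)
    W[upper.tri(W)] <- w
    W <- W + t(W)
    if (.is_connected(W > 0)) return(connectome(W, "structural"))
  }
  stop(sprintf("could not draw a connected topology in %d retries",
               max_retries))
}

.is_connected <- function(adj) {
  n <- nrow(adj)
  visited <- logical(n)
  frontier <- 1L
  visited[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !visited)
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited)
}

#' Per-scan structural connectome from a base topology
#'
#' Multiplies each base edge by an iid log-normal factor (log-scale SD
#' `subject_sigma`) and zeroes a random `dropout` fraction of the present
#' edges, giving the across-scan edge-weight variability consumed by the
#' consistency-thresholding stage.
#'
#' @param base Base structural [connectome].
#' @param subject_sigma Log-scale SD of the multiplicative edge noise.
#' @param dropout Fraction of present edges zeroed per scan.
#' @param seed Optional seed (`NULL`: current RNG state).
#' @return A structural [connectome].
#' @export
simulate_sc <- function(base, subject_sigma = 0.3, dropout = 0.05,
                        seed = NULL) {
  stopifnot(is_connectome(base))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(base$weights)
  ut <- upper.tri(base$weights)
  w <- base$weights[ut]
  present <- which(w > 0)
  if (subject_sigma > 0)
    w[present] <- w[present] *
      stats::rlnorm(length(present), 0, subject_sigma)
  if (dropout > 0) {
    drop_edges <- present[stats::runif(length(present)) < dropout]
    w[drop_edges] <- 0
  }
  W <- matrix(0, n, n)
  W[ut] <- w
  W <- W + t(W)
  connectome(W, "structural", node_ids = base$node_ids)
}

#' Functional connectome with planted regional coupling
#'
#' For each region, builds a latent profile over its non-zero structural
#' neighbours as `r * z + sqrt(1 - r^2) * eps`, where `z` are the Gaussian
#' scores of the structural ranks and `r = calibrate_copula(target)`;
#' structurally absent entries get small-magnitude latent noise. Latent
#' values are squashed into (-1, 1) by `tanh` and the matrix is symmetrized
#' by averaging the (i, j) and (j, i) constructions. The noise innovation
#' is shared across each undirected pair. Regions with fewer than 3
#' non-zero structural edges get a pure-noise profile and are recorded in
#' the `"skipped_nodes"` attribute.
#'
#' @param sc Structural [connectome].
#' @param targets Per-region Spearman targets in (-1, 1) for the row
#'   construction.
#' @param zero_noise_sd Latent SD for structurally absent entries.
#' @param seed Optional seed (`NULL`: current RNG state).
#' @return A functional [connectome] with attribute `skipped_nodes`.
#' @export
simulate_fc_given_sc <- function(sc, targets, zero_noise_sd = 0.3,
                                 seed = NULL) {
  stopifnot(is_connectome(sc))
  n <- nrow(sc$weights)
  if (length(targets) != n) stop("need one target per region")
  if (any(abs(targets) >= 1)) stop("targets must lie in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  Em <- matrix(0, n, n)
  Em[upper.tri(Em)] <- stats::rnorm(n * (n - 1) / 2)
  Em <- Em + t(Em)
  A <- matrix(0, n, n)
  skipped <- integer(0)
  r_all <- calibrate_copula(targets)
  for (i in seq_len(n)) {
    nz <- which(sc$weights[i, ] > 0)
    nz <- nz[nz != i]
    others <- setdiff(seq_len(n)[-i], nz)
    r <- r_all[i]
    if (length(nz) < 3) {
      r <- 0
      skipped <- c(skipped, i)
    }
    if (length(nz)) {
      u <- (rank(sc$weights[i, nz], ties.method = "average") - 0.5) /
        length(nz)
      A[i, nz] <- r * stats::qnorm(u) + sqrt(1 - r^2) * Em[i, nz]
    }
    if (length(others))
      A[i, others] <- zero_noise_sd * Em[i, others]
  }
  M <- tanh(A)
  Fw <- (M + t(M)) / 2
  diag(Fw) <- 0
  out <- connectome(Fw, "functional", node_ids = sc$node_ids)
  attr(out, "skipped_nodes") <- skipped
  out
}

#' Simulate a full longitudinal coupling study
#'
#' Generates the cohort table, a shared base topology, per-scan structural
#' connectomes and functional connectomes with planted regional coupling
#' targets (scenario trajectory + subject-by-region random intercept +
#' covariate effects + residual noise, clipped to \[-0.95, 0.95\]). When
#' `config$compensate` is `TRUE`, the row-construction targets are
#' pre-compensated for the attenuation caused by symmetrizing the
#' functional matrix, so measured coupling tracks the planted target.
#'
#' @param config A [sim_config].
#' @return List with `cohort`, `sc` and `fc` (lists parallel to cohort
#'   rows), `targets` (scan x region matrix of planted targets), `truth`
#'   (scenario kind per region plus the scenario map) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cohort <- simulate_cohort(config, seed = NA)
  base <- make_base_topology(config$n_nodes, config$density,
                             config$n_communities)
  n_scan <- nrow(cohort)
  subj <- factor(cohort$subject_id)
  re <- matrix(stats::rnorm(nlevels(subj) * config$n_nodes,
                            0, config$subject_sd),
               nlevels(subj), config$n_nodes)
  cb <- config$cov_beta
  sc_list <- vector("list", n_scan)
  fc_list <- vector("list", n_scan)
  targets <- matrix(NA_real_, n_scan, config$n_nodes)
  # symmetrization mixes each row construction with its neighbours';
  # compensate by solving (I + A) x = 2 target on the base topology
  # (row-normalized adjacency A, damped Jacobi iterations)
  adj <- (base$weights > 0) * 1
  deg <- pmax(rowSums(adj), 1)
  for (s in seq_len(n_scan)) {
    row <- cohort[s, ]
    sc_s <- simulate_sc(base, config$subject_sigma, config$dropout)
    tgt <- vapply(config$scenario_map, target_coupling,
                  numeric(1), group = row$group, age = row$age)
    cov_eff <- cb[["fd_dwi"]] * row$fd_dwi + cb[["fd_fmri"]] * row$fd_fmri +
      cb[["scanner"]] * (row$scanner == "post_upgrade") +
      cb[["sex"]] * (row$sex == "female") +
      cb[["medicated"]] * row$medicated
    tgt <- tgt + re[as.integer(subj)[s], ] + cov_eff +
      stats::rnorm(config$n_nodes, 0, config$noise_sd)
    tgt <- pmin(pmax(tgt, -0.95), 0.95)
    row_tgt <- tgt
    if (config$compensate) {
      x <- tgt
      for (it in 1:20)
        x <- 0.5 * x + 0.5 * (2 * tgt - drop(adj %*% x) / deg)
      row_tgt <- pmin(pmax(x, -0.95), 0.95)
    }
    fc_list[[s]] <- simulate_fc_given_sc(sc_s, row_tgt,
                                         config$zero_noise_sd)
    sc_list[[s]] <- sc_s
    targets[s, ] <- tgt
  }
  kinds <- vapply(config$scenario_map, `[[`, character(1), "kind")
  list(cohort = cohort, sc = sc_list, fc = fc_list, targets = targets,
       truth = list(kind = kinds, scenario_map = config$scenario_map),
       base = base, config = config)
}

#' Simulate a coupling table directly at the statistic level
#'
#' Skips connectome generation: per-region coupling values are drawn as
#' planted target + subject-by-region random intercept + covariate effects
#' + iid noise. Useful for large calibration experiments on the trajectory
#' models (e.g. type-I error at hundreds of regions) where the connectome
#' stage would only add cost.
#'
#' @param cohort Validated cohort data frame.
#' @param scenarios List of [scenario]s, one per simulated region.
#' @param noise_sd Residual SD of the coupling value (includes measurement
#'   noise).
#' @param subject_sd SD of the subject-by-region random intercept.
#' @param cov_beta Named covariate effects (see [sim_config()]).
#' @param seed Optional seed.
#' @return Long coupling table with the [coupling_dataset()] columns.
#' @export
simulate_coupling_table <- function(cohort, scenarios, noise_sd = 0.1,
                                    subject_sd = 0.03,
                                    cov_beta = c(fd_dwi = 0, fd_fmri = -0.10,
                                                 scanner = 0.02, sex = 0,
                                                 medicated = 0),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_reg <- length(scenarios)
  subj <- factor(cohort$subject_id)
  re <- matrix(stats::rnorm(nlevels(subj) * n_reg, 0, subject_sd),
               nlevels(subj), n_reg)
  cov_eff <- cov_beta[["fd_dwi"]] * cohort$fd_dwi +
    cov_beta[["fd_fmri"]] * cohort$fd_fmri +
    cov_beta[["scanner"]] * (cohort$scanner == "post_upgrade") +
    cov_beta[["sex"]] * (cohort$sex == "female") +
    cov_beta[["medicated"]] * cohort$medicated
  out <- vector("list", n_reg)
  for (r in seq_len(n_reg)) {
    tgt <- vapply(seq_len(nrow(cohort)), function(s)
      target_coupling(scenarios[[r]], cohort$group[s], cohort$age[s]),
      numeric(1))
    rho <- tgt + re[as.integer(subj), r] + cov_eff +
      stats::rnorm(nrow(cohort), 0, noise_sd)
    out[[r]] <- data.frame(cohort, region = r,
                           rho = pmin(pmax(rho, -0.99), 0.99),
                           n_edges_used = NA_integer_,
                           row.names = NULL)
  }
  tab <- do.call(rbind, out)
  tab$missing <- is.na(tab$rho)
  rownames(tab) <- NULL
  tab
}
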