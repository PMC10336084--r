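# Regional developmental trajectory models.
#
# Both entry points consume the long coupling table from coupling_dataset()
# (or simulate_coupling_table()) and fit, per region, penalized-spline
# GAMMs with subject random intercepts by exact marginal ML. Nuisance
# covariates follow the study design: dwi and fmri head motion, scanner
# upgrade, sex, medication.

.covariate_design <- function(d) {
  X <- cbind(
    intercept = 1,
    fd_dwi = d$fd_dwi,
    fd_fmri = d$fd_fmri,
    scanner_post = as.numeric(d$scanner == "post_upgrade"),
    sex_female = as.numeric(d$sex == "female"),
    medicated = as.numeric(d$medicated)
  )
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(col) stats::sd(col) > 0))
  list(X = X[, keep, drop = FALSE],
       dropped = colnames(X)[!keep])
}

.region_rows <- function(tab, region) {
  d <- tab[tab$region == region & !is.na(tab$rho), , drop = FALSE]
  d
}

# population-level fitted trajectory at mean covariates, for a fit whose
# only smooth is the age basis (fixed design = covariates only)
.trajectory <- function(fit, basis, X_cov_means, ages) {
  pr <- stats::predict(basis, ages)
  p_cov <- length(X_cov_means)
  rep(sum(X_cov_means * fit$beta[seq_len(p_cov)]), length(ages)) +
    drop(pr$X %*% fit$beta[p_cov + 1L]) +
    drop(pr$Z %*% fit$u_smooth[seq_len(ncol(basis$Z))])
}

#' Age trajectories of coupling in typically developing children
#'
#' For each region, compares a covariates-only null model (M0: head motion,
#' scanner, sex, medication, subject random intercept) against the same
#' model plus a penalized age smooth (M1, basis dimension `k`), both by
#' marginal ML, using rows from the control group only. Age LRT p-values
#' are FDR-adjusted across regions with Benjamini-Hochberg.
#'
#' @param tab Long coupling table (see [coupling_dataset()]).
#' @param regions Regions to model (default: all present in `tab`).
#' @param k Smooth basis dimension (default 4).
#' @param alpha FDR significance level (default 0.05).
#' @param min_rows Minimum usable rows per region (default 10); regions
#'   below it are skipped and listed in the result.
#' @param grid_n Number of ages in the exported fitted trajectories.
#' @return List with `results` (one row per region: `p_age`, `q_age`,
#'   `sig_age`, log-likelihoods, AICs, fitted 9-to-14 change `delta_fit`),
#'   `trajectories` (long data frame of fitted population trajectories from
#'   M1) and `skipped`.
#' @export
run_typical_development <- function(tab, regions = NULL, k = 4,
                                    alpha = 0.05, min_rows = 10,
                                    grid_n = 25) {
  d_all <- tab[tab$group == "control", , drop = FALSE]
  if (!nrow(d_all)) stop("no control rows in table")
  if (is.null(regions)) regions <- sort(unique(d_all$region))
  res <- vector("list", length(regions))
  traj <- vector("list", length(regions))
  skipped <- data.frame(region = integer(0), reason = character(0))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    d <- .region_rows(d_all, r)
    if (nrow(d) < min_rows) {
      skipped <- rbind(skipped, data.frame(
        region = r, reason = sprintf("only %d usable rows", nrow(d))))
      next
    }
    cov <- .covariate_design(d)
    basis <- spline_basis(d$age, k = k)
    m0 <- fit_gamm(d$rho, cov$X, subject = d$subject_id, model_id = "M0")
    m1 <- fit_gamm(d$rho, cov$X, subject = d$subject_id,
                   smooths = list(basis), model_id = "M1")
    tst <- lrt(m0, m1)
    ages <- seq(min(d$age), max(d$age), length.out = grid_n)
    cov_means <- colMeans(cov$X)
    fitted_line <- .trajectory(m1, basis, cov_means, ages)
    res[[ri]] <- data.frame(
      region = r, n = nrow(d),
      loglik_m0 = m0$loglik, loglik_m1 = m1$loglik,
      aic_m0 = m0$aic, aic_m1 = m1$aic,
      edf_m1 = m1$edf,
      p_age = tst$p,
      delta_fit = fitted_line[grid_n] - fitted_line[1],
      converged = m0$converged && m1$converged
    )
    traj[[ri]] <- data.frame(region = r, age = ages, fitted = fitted_line)
  }
  results <- do.call(rbind, res)
  if (is.null(results)) stop("no region had enough usable rows")
  fdr <- bh_fdr(results$p_age, alpha = alpha)
  results$q_age <- fdr$q
  results$sig_age <- fdr$rejected
  rownames(results) <- NULL
  list(results = results,
       trajectories = do.call(rbind, traj),
       skipped = skipped,
       settings = list(k = k, alpha = alpha, min_rows = min_rows,
                       analysis = "typical"))
}

#' Group and group-by-age model ladder across regions
#'
#' Fits the four nested models per region on the full sample: M0
#' (covariates + subject random intercept), M1 (+ age smooth), M2 (+ group
#' main effect), M3 (+ group-specific smooth deviation, so M2 is nested in
#' M3). Models are compared by sequential forward LRT/AIC selection
#' ([select_model()]); each contrast's p-values are FDR-adjusted across
#' regions separately (age, group, interaction families).
#'
#' @inheritParams run_typical_development
#' @param aic_margin Required AIC improvement per ladder step (default 2).
#' @param selection_mode Passed to [select_model()] (`"forward"` or
#'   `"strict"`).
#' @return List with `results` (per region: stage p/q values, significance
#'   flags, selected model, the M2 group coefficient `beta_group`),
#'   `trajectories` (fitted M3 population trajectories per group) and
#'   `skipped`.
#' @export
run_group_ladder <- function(tab, regions = NULL, k = 4, alpha = 0.05,
                             aic_margin = 2, min_rows = 10, grid_n = 25,
                             selection_mode = c("forward", "strict")) {
  selection_mode <- match.arg(selection_mode)
  if (is.null(regions)) regions <- sort(unique(tab$region))
  res <- vector("list", length(regions))
  traj <- vector("list", length(regions))
  skipped <- data.frame(region = integer(0), reason = character(0))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    d <- .region_rows(tab, r)
    if (nrow(d) < min_rows || length(unique(d$group)) < 2) {
      skipped <- rbind(skipped, data.frame(
        region = r,
        reason = if (nrow(d) < min_rows)
          sprintf("only %d usable rows", nrow(d))
        else "a group is absent"))
      next
    }
    cov <- .covariate_design(d)
    adhd <- as.numeric(d$group == "adhd")
    basis <- spline_basis(d$age, k = k)
    diff_smooth <- list(X = basis$X * adhd, Z = basis$Z * adhd)
    X2 <- cbind(cov$X, group_adhd = adhd)
    m0 <- fit_gamm(d$rho, cov$X, subject = d$subject_id, model_id = "M0")
    m1 <- fit_gamm(d$rho, cov$X, subject = d$subject_id,
                   smooths = list(basis), model_id = "M1")
    m2 <- fit_gamm(d$rho, X2, subject = d$subject_id,
                   smooths = list(basis), model_id = "M2")
    m3 <- fit_gamm(d$rho, X2, subject = d$subject_id,
                   smooths = list(basis, diff_smooth), model_id = "M3")
    sel <- select_model(list(m0, m1, m2, m3), alpha = alpha,
                        aic_margin = aic_margin, mode = selection_mode)
    t_age <- lrt(m0, m1); t_grp <- lrt(m1, m2); t_int <- lrt(m2, m3)
    ages <- seq(min(d$age), max(d$age), length.out = grid_n)
    cov_means <- colMeans(cov$X)
    pr <- stats::predict(basis, ages)
    nz <- ncol(basis$Z)
    p_cov <- ncol(cov$X)
    base_line <- rep(sum(cov_means * m3$beta[seq_len(p_cov)]), grid_n) +
      drop(pr$X %*% m3$beta[p_cov + 2L]) +
      drop(pr$Z %*% m3$u_smooth[seq_len(nz)])
    adhd_line <- base_line + m3$beta[p_cov + 1L] +
      drop(pr$X %*% m3$beta[p_cov + 3L]) +
      drop(pr$Z %*% m3$u_smooth[nz + seq_len(nz)])
    res[[ri]] <- data.frame(
      region = r, n = nrow(d),
      loglik_m0 = m0$loglik, loglik_m1 = m1$loglik,
      loglik_m2 = m2$loglik, loglik_m3 = m3$loglik,
      aic_m0 = m0$aic, aic_m1 = m1$aic, aic_m2 = m2$aic, aic_m3 = m3$aic,
      p_age = t_age$p, p_group = t_grp$p, p_interaction = t_int$p,
      beta_group = unname(m2$beta["group_adhd"]),
      selected = sel$selected,
      converged = all(vapply(list(m0, m1, m2, m3), `[[`,
                             logical(1), "converged"))
    )
    traj[[ri]] <- data.frame(
      region = r, age = rep(ages, 2),
      group = rep(c("control", "adhd"), each = grid_n),
      fitted = c(base_line, adhd_line))
  }
  results <- do.call(rbind, res)
  if (is.null(results)) stop("no region had enough usable rows")
  for (fam in c("age", "group", "interaction")) {
    fdr <- bh_fdr(results[[paste0("p_", fam)]], alpha = alpha)
    results[[paste0("q_", fam)]] <- fdr$q
    results[[paste0("sig_", fam)]] <- fdr$rejected
  }
  rownames(results) <- NULL
  list(results = results,
       trajectories = do.call(rbind, traj),
       skipped = skipped,
       settings = list(k = k, alpha = alpha, aic_margin = aic_margin,
                       min_rows = min_rows, analysis = "group",
                       selection_mode = selection_mode))
}
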