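#' Pipeline run configuration
#'
#' Bundles the study analysis settings (motion exclusion at 0.5 mm,
#' consistency thresholding at the 75th percentile, smooth basis dimension
#' 4, alpha 0.05, AIC margin 2) with the input source: either an in-memory
#' synthetic study ([sim_config()]) or on-disk inputs (cohort CSV plus
#' per-scan connectome files named `{subject}_{wave}_{sc|fc}.csv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param sim Optional [sim_config]; when given, inputs are simulated.
#' @param cohort_csv,sc_dir,fc_dir On-disk inputs (ignored when `sim` is
#'   given).
#' @param percentile Consistency-threshold percentile.
#' @param min_edges Minimum non-zero edges for a defined coupling value.
#' @param fd_limit Motion exclusion threshold (mm).
#' @param alpha Significance level for LRT and FDR.
#' @param aic_margin AIC improvement required per ladder step.
#' @param k Smooth basis dimension.
#' @param analysis `"typical"`, `"group"` or `"both"`.
#' @param seed Integer seed for any simulation.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sim = NULL, cohort_csv = NULL,
                       sc_dir = NULL, fc_dir = NULL,
                       percentile = 75, min_edges = 3, fd_limit = 0.5,
                       alpha = 0.05, aic_margin = 2, k = 4,
                       analysis = c("both", "typical", "group"),
                       seed = 1L) {
  analysis <- match.arg(analysis)
  if (is.null(sim) && is.null(cohort_csv))
    stop("either `sim` or `cohort_csv` (+ sc_dir/fc_dir) must be given")
  stopifnot(percentile > 0, percentile < 100, min_edges >= 3,
            fd_limit > 0, alpha > 0, alpha < 1, k >= 4)
  structure(list(out_dir = out_dir, sim = sim, cohort_csv = cohort_csv,
                 sc_dir = sc_dir, fc_dir = fc_dir,
                 percentile = percentile, min_edges = min_edges,
                 fd_limit = fd_limit, alpha = alpha,
                 aic_margin = aic_margin, k = k, analysis = analysis,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full coupling pipeline
#'
#' Chains motion QC, consistency thresholding of the structural scans,
#' regional coupling, and the developmental trajectory analyses, writing
#' every stage's outputs and a manifest (settings, stage counts, content
#' hash per output file) into `config$out_dir`. Re-running with the same
#' configuration and inputs reproduces all result files byte-identically.
#'
#' @param config A [run_config].
#' @param quiet Suppress stage progress messages.
#' @return (Invisibly) a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- .write_csv(df, file.path(config$out_dir, name))
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    say("stage simulate: seed %d, %d + %d subjects, %d nodes",
        config$sim$seed, config$sim$n_adhd, config$sim$n_control,
        config$sim$n_nodes)
    study <- simulate_study(config$sim)
    cohort <- study$cohort
    sc_list <- study$sc
    fc_list <- study$fc
    truth <- study$truth
    emit(cohort, "cohort.csv")
  } else {
    cohort <- read_cohort(config$cohort_csv)
    files <- function(dir, tag) {
      p <- file.path(dir, sprintf("%s_%d_%s.csv", cohort$subject_id,
                                  cohort$wave, tag))
      miss <- !file.exists(p)
      if (any(miss))
        stop(sprintf("stage read: scan(s) without both matrices: %s",
                     paste(basename(p[miss]), collapse = ", ")))
      p
    }
    sc_list <- lapply(files(config$sc_dir, "sc"), read_connectome,
                      modality = "structural")
    fc_list <- lapply(files(config$fc_dir, "fc"), read_connectome,
                      modality = "functional")
  }

  # --- QC -------------------------------------------------------------
  qc <- qc_filter(cohort, fd_limit = config$fd_limit)
  keep_idx <- which(cohort$fd_fmri <= config$fd_limit)
  say("stage qc: %d scans kept, %d excluded (fd > %.2f mm)",
      nrow(qc$kept), nrow(qc$excluded), config$fd_limit)
  sc_list <- sc_list[keep_idx]
  fc_list <- fc_list[keep_idx]
  cohort <- qc$kept
  emit(cohort, "cohort_kept.csv")
  emit(qc$excluded, "qc_excluded.csv")

  # --- consistency thresholding --------------------------------------
  cv <- edge_cv(sc_list)
  mask <- consistency_mask(cv, percentile = config$percentile)
  excl <- excluded_nodes(mask)
  say("stage threshold: %d / %d edges kept (CV <= %.4g), %d node(s) excluded",
      mask$n_kept_edges, mask$n_candidate_edges, mask$cv_threshold,
      length(excl))
  mask_df <- as.data.frame(mask$mask)
  names(mask_df) <- paste0("n", seq_len(ncol(mask_df)))
  emit(mask_df, "mask.csv")

  # --- regional coupling ---------------------------------------------
  tab <- coupling_dataset(cohort, sc_list, fc_list, mask = mask,
                          min_edges = config$min_edges)
  say("stage couple: %d rows (%d scans x %d regions), %d missing",
      nrow(tab), nrow(cohort), length(unique(tab$region)),
      sum(tab$missing))
  emit(tab, "coupling.csv")

  # --- trajectories ---------------------------------------------------
  typical <- group <- NULL
  if (config$analysis %in% c("typical", "both")) {
    typical <- run_typical_development(tab, k = config$k,
                                       alpha = config$alpha)
    say("stage fit (typical): %d regions, %d FDR-significant age effects",
        nrow(typical$results), sum(typical$results$sig_age, na.rm = TRUE))
    emit(typical$results, "results_typical.csv")
    emit(typical$trajectories, "trajectories_typical.csv")
  }
  if (config$analysis %in% c("group", "both")) {
    group <- run_group_ladder(tab, k = config$k, alpha = config$alpha,
                              aic_margin = config$aic_margin)
    say("stage fit (group): %d regions; selected models: %s",
        nrow(group$results),
        paste(names(table(group$results$selected)),
              table(group$results$selected), collapse = " ", sep = "="))
    emit(group$results, "results_group.csv")
    emit(group$trajectories, "trajectories_group.csv")
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(
    settings = list(
      percentile = config$percentile, min_edges = config$min_edges,
      fd_limit = config$fd_limit, alpha = config$alpha,
      aic_margin = config$aic_margin, k = config$k,
      analysis = config$analysis, seed = config$seed,
      simulated = !is.null(config$sim),
      sim_seed = if (!is.null(config$sim)) config$sim$seed
    ),
    counts = list(
      scans_in = nrow(qc$kept) + nrow(qc$excluded),
      scans_excluded_qc = nrow(qc$excluded),
      scans_analyzed = nrow(cohort),
      edges_candidate = mask$n_candidate_edges,
      edges_kept = mask$n_kept_edges,
      cv_threshold = mask$cv_threshold,
      nodes_excluded = length(excl),
      coupling_rows = nrow(tab),
      coupling_missing = sum(tab$missing)
    ),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(md5 = unname(tools::md5sum(p)))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, mask = mask, excluded_nodes = excl,
                 coupling = tab, typical = typical, group = group,
                 truth = truth, manifest = manifest))
}

#' Descriptive roll-up of regional results by functional network
#'
#' Counts FDR-significant regions per contrast within each atlas network
#' label and averages the fitted coupling change (columns are used when
#' present in `results`). Purely descriptive; no inference.
#'
#' @param results Per-region results data frame from
#'   [run_typical_development()] or [run_group_ladder()].
#' @param atlas Atlas data frame (see [read_atlas()]) with a `network`
#'   column.
#' @return Data frame with one row per network; regions absent from the
#'   atlas are listed in the `"unmapped"` attribute.
#' @export
summarize_by_network <- function(results, atlas) {
  stopifnot(is.data.frame(results), is.data.frame(atlas))
  unmapped <- setdiff(results$region, atlas$node_id)
  m <- merge(results, atlas[, c("node_id", "network")],
             by.x = "region", by.y = "node_id")
  m$network[is.na(m$network) | m$network == ""] <- "unlabelled"
  nets <- sort(unique(m$network))
  sig_cols <- intersect(c("sig_age", "sig_group", "sig_interaction"),
                        names(m))
  out <- do.call(rbind, lapply(nets, function(nw) {
    d <- m[m$network == nw, , drop = FALSE]
    row <- data.frame(network = nw, n_regions = nrow(d))
    for (sc in sig_cols)
      row[[paste0("n_", sc)]] <- sum(d[[sc]], na.rm = TRUE)
    row$mean_delta_fit <- if ("delta_fit" %in% names(d))
      mean(d$delta_fit, na.rm = TRUE) else NA_real_
    row
  }))
  attr(out, "unmapped") <- unmapped
  out
}
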