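#' Spearman rank correlation
#'
#' Ties receive average ranks; the statistic is the Pearson correlation of
#' the two rank vectors. Returns `NA` when either vector is constant (rank
#' correlation undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return Spearman's rho in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3)
    stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Regional structure-function coupling for one scan
#'
#' For each region, the coupling statistic is the Spearman rank correlation
#' between the region's structural connectivity profile and its functional
#' connectivity profile, restricted to the entries where the (masked)
#' structural weight is non-zero. FC zeros are legitimate correlation values
#' and are not excluded. A region's coupling is missing when it has fewer
#' than `min_edges` non-zero structural edges or appears in
#' `excluded`.
#'
#' @param sc Structural [connectome] (already masked).
#' @param fc Functional [connectome], same node order.
#' @param min_edges Minimum number of non-zero structural edges for a
#'   defined coupling value (default 3).
#' @param excluded Integer vector of node indices excluded group-wide.
#' @return A `coupling_profile`: list with `rho` (length-n vector, `NA`
#'   where undefined), `n_edges_used`, `excluded_nodes`.
#' @export
regional_coupling <- function(sc, fc, min_edges = 3, excluded = integer(0)) {
  stopifnot(is_connectome(sc), is_connectome(fc))
  if (sc$modality != "structural" || fc$modality != "functional")
    stop("expected one structural and one functional connectome")
  n <- nrow(sc$weights)
  if (nrow(fc$weights) != n)
    stop("sc and fc dimensions differ")
  rho <- rep(NA_real_, n)
  m_used <- integer(n)
  for (i in seq_len(n)) {
    sel <- which(sc$weights[i, ] > 0)
    sel <- sel[sel != i]
    m_used[i] <- length(sel)
    if (i %in% excluded || length(sel) < min_edges) next
    rho[i] <- spearman_rho(sc$weights[i, sel], fc$weights[i, sel])
  }
  structure(list(rho = rho, n_edges_used = m_used,
                 excluded_nodes = as.integer(excluded)),
            class = "coupling_profile")
}

#' Long coupling table for a set of scans
#'
#' Computes [regional_coupling()] for every scan and assembles the single
#' long table consumed by the trajectory models: one row per (scan,
#' non-excluded region), carrying the scan's covariates and the regional
#' coupling value (rows with undefined coupling are retained with
#' `missing = TRUE`).
#'
#' @param records Validated cohort data frame (the scans to process).
#' @param sc_list,fc_list Lists of structural / functional [connectome]s,
#'   parallel to the rows of `records`. Structural scans should already be
#'   masked (see [apply_mask()]).
#' @param mask Optional `edge_mask`; if supplied, it is applied to each
#'   structural scan and its disconnected nodes are excluded.
#' @param min_edges Passed to [regional_coupling()].
#' @return Data frame with columns `subject_id`, `group`, `wave`, `age`,
#'   `sex`, `medicated`, `fd_dwi`, `fd_fmri`, `scanner`, `region`, `rho`,
#'   `n_edges_used`, `missing`.
#' @export
coupling_dataset <- function(records, sc_list, fc_list, mask = NULL,
                             min_edges = 3) {
  stopifnot(is.data.frame(records))
  if (length(sc_list) != nrow(records) || length(fc_list) != nrow(records)) {
    missing_sc <- nrow(records) - length(sc_list)
    stop(sprintf(
      "each scan needs both matrices: %d records vs %d sc / %d fc",
      nrow(records), length(sc_list), length(fc_list)))
  }
  excl <- integer(0)
  if (!is.null(mask)) {
    sc_list <- lapply(sc_list, apply_mask, mask = mask)
    excl <- excluded_nodes(mask)
  }
  n <- nrow(sc_list[[1]]$weights)
  regions <- setdiff(seq_len(n), excl)
  out <- vector("list", nrow(records))
  for (s in seq_len(nrow(records))) {
    prof <- regional_coupling(sc_list[[s]], fc_list[[s]],
                              min_edges = min_edges, excluded = excl)
    row <- records[s, , drop = FALSE]
    out[[s]] <- data.frame(
      row[rep(1, length(regions)), , drop = FALSE],
      region = regions,
      rho = prof$rho[regions],
      n_edges_used = prof$n_edges_used[regions],
      row.names = NULL
    )
  }
  tab <- do.call(rbind, out)
  tab$missing <- is.na(tab$rho)
  rownames(tab) <- NULL
  tab
}
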