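#' Edge-wise coefficient of variation across structural connectomes
#'
#' For every edge, computes sd/mean of its weight over all supplied scans
#' (sample sd, n - 1 denominator). Zero weights count as observed values:
#' an edge absent from some scans is, by design, inconsistent. Edges with
#' mean weight 0 (absent everywhere) get an `Inf` sentinel so that they can
#' never be kept by [consistency_mask()].
#'
#' @param scans List of structural [connectome]s with identical node order.
#' @return Symmetric n x n matrix of CVs (diagonal 0).
#' @export
edge_cv <- function(scans) {
  if (length(scans) < 2) stop("need at least 2 scans to compute edge CV")
  stopifnot(all(vapply(scans, is_connectome, logical(1))))
  n <- nrow(scans[[1]]$weights)
  dims <- vapply(scans, function(s) nrow(s$weights), integer(1))
  if (any(dims != n))
    stop("mismatched connectome dimensions across scans")
  ut <- upper.tri(matrix(0, n, n))
  W <- vapply(scans, function(s) s$weights[ut],
              numeric(sum(ut)))           # edges x scans
  mu <- rowMeans(W)
  sdv <- apply(W, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, Inf)
  out <- matrix(0, n, n)
  out[ut] <- cv
  out <- out + t(out)
  diag(out) <- 0
  out
}

#' Consistency-based edge mask
#'
#' Keeps the most consistent edges: candidate edges are those with a finite
#' CV (present in at least one scan); the threshold is the linearly
#' interpolated (type-7) `percentile`-th percentile of candidate CVs, and
#' candidates with CV less than or equal to the threshold are kept -- i.e.
#' the 75 percent lowest-variability edges at the default setting.
#'
#' @param cv Symmetric CV matrix from [edge_cv()].
#' @param percentile Percentile of the candidate CV distribution used as the
#'   cutoff (default 75).
#' @return An `edge_mask` object: list with `mask` (binary symmetric
#'   matrix), `cv_threshold`, `n_candidate_edges`, `n_kept_edges`.
#' @export
consistency_mask <- function(cv, percentile = 75) {
  if (!is.matrix(cv) || nrow(cv) != ncol(cv))
    stop("`cv` must be a square matrix")
  if (max(abs(cv - t(cv))[is.finite(cv - t(cv))]) > 1e-12 ||
      any(is.finite(cv) != is.finite(t(cv))))
    stop("`cv` must be symmetric")
  n <- nrow(cv)
  ut <- upper.tri(cv)
  vals <- cv[ut]
  cand <- is.finite(vals)
  if (!any(cand)) stop("no candidate edges with finite CV")
  thr <- stats::quantile(vals[cand], probs = percentile / 100,
                         type = 7, names = FALSE)
  keep <- cand & vals <= thr
  mask <- matrix(0L, n, n)
  mask[ut][keep] <- 1L
  mask <- mask + t(mask)
  structure(list(mask = mask, cv_threshold = thr,
                 n_candidate_edges = sum(cand),
                 n_kept_edges = sum(keep)),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf(
    "<edge_mask: %d / %d candidate edges kept (CV threshold %.4g)>\n",
    x$n_kept_edges, x$n_candidate_edges, x$cv_threshold))
  invisible(x)
}

#' Apply an edge mask to a connectome
#'
#' @param scan A [connectome].
#' @param mask An `edge_mask` from [consistency_mask()].
#' @return The connectome with weights zeroed where the mask is 0.
#' @export
apply_mask <- function(scan, mask) {
  stopifnot(is_connectome(scan), inherits(mask, "edge_mask"))
  if (!all(dim(scan$weights) == dim(mask$mask)))
    stop("connectome and mask dimensions differ")
  scan$weights <- scan$weights * mask$mask
  scan
}

#' Nodes disconnected by the group mask
#'
#' Regions whose masked row is all zero in the shared group mask have no
#' surviving structural edges in any scan; they are excluded from regional
#' coupling for all scans.
#'
#' @param mask An `edge_mask`.
#' @return Integer vector of excluded node indices (possibly empty).
#' @export
excluded_nodes <- function(mask) {
  stopifnot(inherits(mask, "edge_mask"))
  which(rowSums(mask$mask) == 0)
}
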