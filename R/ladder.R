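#' Likelihood-ratio test between two nested ML fits
#'
#' The deviance `2 * (loglik_complex - loglik_simple)` is clipped at zero
#' (a numerically lower complex-model likelihood counts as no improvement)
#' and referred to a chi-square with `n_fixed(complex) - n_fixed(simple)`
#' degrees of freedom. Counting unconstrained smooth basis columns in
#' `n_fixed` makes the df an upper bound for penalized terms, so the test
#' is conservative.
#'
#' @param simple,complex `gamm_fit` objects fitted by ML on identical rows,
#'   with `simple` nested in `complex`.
#' @return List with `deviance`, `df` and `p`.
#' @export
lrt <- function(simple, complex) {
  stopifnot(inherits(simple, "gamm_fit"), inherits(complex, "gamm_fit"))
  if (simple$n != complex$n ||
      max(abs(simple$y_fingerprint - complex$y_fingerprint)) > 1e-8)
    stop("fits are not on identical rows")
  df <- complex$n_fixed - simple$n_fixed
  if (df <= 0) stop("models are not nested (complex must add parameters)")
  dev <- max(0, 2 * (complex$loglik - simple$loglik))
  p <- stats::pchisq(dev, df = df, lower.tail = FALSE)
  list(deviance = dev, df = df, p = p)
}

#' Forward model selection over the nested ladder
#'
#' Walks the ladder M0 -> M1 -> M2 -> M3 (or however many fits are given,
#' in order of increasing complexity). A more complex model is adopted only
#' if the LRT against the currently accepted model is significant
#' (`p < alpha`) AND it improves that model's AIC by at least `aic_margin`
#' units. In the default `"forward"` mode a failed stage does not end the
#' walk: the next candidate is still tested against the accepted model
#' (every pair along the ladder is nested, so e.g. a null-vs-group test is
#' well defined even when the age stage failed -- necessary for effects,
#' such as a pure group offset, that skip a rung). `mode = "strict"` stops
#' at the first failure. Non-converged fits end the walk in either mode.
#'
#' @param fits Ordered list of nested `gamm_fit` objects (simplest first).
#' @param alpha LRT significance level (default 0.05).
#' @param aic_margin Required AIC improvement in units (default 2).
#' @param mode `"forward"` (default) or `"strict"`; see Details.
#' @return List with `selected` (the chosen model's `model_id`),
#'   `selected_index`, and per-stage `p` and `delta_aic` vectors (each
#'   stage's candidate tested against the model accepted when it was
#'   reached).
#' @export
select_model <- function(fits, alpha = 0.05, aic_margin = 2,
                         mode = c("forward", "strict")) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1)
  n_stage <- length(fits) - 1L
  p <- rep(NA_real_, n_stage)
  dAIC <- rep(NA_real_, n_stage)
  current <- 1L
  for (stage in seq_len(n_stage)) {
    cand <- stage + 1L
    if (!fits[[cand]]$converged) break
    tst <- lrt(fits[[current]], fits[[cand]])
    p[stage] <- tst$p
    dAIC[stage] <- fits[[cand]]$aic - fits[[current]]$aic
    if (tst$p < alpha && dAIC[stage] <= -aic_margin) {
      current <- cand
    } else if (mode == "strict") break
  }
  list(selected = fits[[current]]$model_id, selected_index = current,
       p = p, delta_aic = dAIC)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: `q(i) = min_{j >= rank(i)} m * p(j) / j`, capped at
#' 1. Missing p-values are passed through as missing and do not count
#' toward `m`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param alpha Rejection level on the adjusted values (default 0.05).
#' @return List with `q` (adjusted values) and `rejected`
#'   (`q <= alpha`; `NA` where the input was missing).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  list(q = q, rejected = q <= alpha)
}
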