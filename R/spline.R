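#' Penalized cubic spline basis for an age smooth
#'
#' Builds a cubic B-spline basis of dimension `k` (knots at age quantiles
#' for k > 4; k = 4 spans the cubic polynomials on the observed range) with
#' a second-order smoothness penalty and a sum-to-zero centering constraint,
#' the standard construction for a smooth term inside a mixed model.
#'
#' The penalty is formed from second-order divided differences of the
#' basis coefficients with respect to the Greville abscissae, so its null
#' space maps exactly onto functions linear in age (B-spline linear
#' precision). After centering (which absorbs the constant into the model
#' intercept) the basis is reparameterized into one unpenalized column --
#' the centered linear age trend -- and `k - 2` penalized columns with an
#' identity penalty, ready to enter a mixed model as fixed and random
#' effects respectively. As the smoothing parameter grows the fit therefore
#' collapses onto the ordinary least-squares line in age.
#'
#' @param ages Numeric vector of ages (years); at least `k` distinct values.
#' @param k Basis dimension (default 4, >= 4 for a cubic basis).
#' @return A `spline_basis` object with elements `X` (m x 1 unpenalized
#'   linear column), `Z` (m x (k-2) penalized columns, identity penalty),
#'   plus the transform needed by `predict()`.
#' @export
spline_basis <- function(ages, k = 4) {
  if (k < 4) stop("k must be >= 4 for a cubic basis")
  ux <- unique(ages)
  if (length(ux) < k)
    stop(sprintf("need at least k = %d distinct ages, got %d",
                 k, length(ux)))
  degree <- 3
  n_interior <- k - degree - 1
  interior <- if (n_interior > 0) {
    stats::quantile(ages, probs = seq_len(n_interior) / (n_interior + 1),
                    type = 7, names = FALSE)
  } else numeric(0)
  bounds <- range(ages)
  knots <- c(rep(bounds[1], degree + 1), interior, rep(bounds[2], degree + 1))
  B <- splines::splineDesign(knots, ages, ord = degree + 1)

  # Greville abscissae: the sites whose linear combination reproduces x
  tau <- vapply(seq_len(k),
                function(j) mean(knots[(j + 1):(j + degree)]), numeric(1))
  D <- matrix(0, k - 2, k)
  for (j in seq_len(k - 2)) {
    t0 <- tau[j]; t1 <- tau[j + 1]; t2 <- tau[j + 2]
    D[j, j]     <- 2 / ((t1 - t0) * (t2 - t0))
    D[j, j + 1] <- -2 / ((t1 - t0) * (t2 - t1))
    D[j, j + 2] <- 2 / ((t2 - t1) * (t2 - t0))
  }
  S <- crossprod(D)

  # sum-to-zero constraint over the observed rows
  cvec <- colSums(B)
  Qc <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  Sc <- crossprod(Qc, S %*% Qc)
  eg <- eigen(Sc, symmetric = TRUE)
  ev <- eg$values
  pen <- ev > max(ev) * 1e-10
  if (sum(!pen) != 1)
    stop("unexpected penalty null-space dimension after centering")
  # identity-penalty scaling of the penalized columns
  Tz <- Qc %*% eg$vectors[, pen, drop = FALSE] %*%
    diag(1 / sqrt(ev[pen]), sum(pen))
  Tx <- Qc %*% eg$vectors[, !pen, drop = FALSE]
  structure(list(
    X = B %*% Tx,
    Z = B %*% Tz,
    k = k, knots = knots, degree = degree,
    Tx = Tx, Tz = Tz, bounds = bounds
  ), class = "spline_basis")
}

#' Evaluate a spline basis at new ages
#'
#' Ages outside the training range are clamped to it.
#'
#' @param object A `spline_basis`.
#' @param newages Numeric vector of ages.
#' @param ... Unused.
#' @return List with `X` and `Z` matrices for the new ages.
#' @export
predict.spline_basis <- function(object, newages, ...) {
  x <- pmin(pmax(newages, object$bounds[1]), object$bounds[2])
  B <- splines::splineDesign(object$knots, x, ord = object$degree + 1)
  list(X = B %*% object$Tx, Z = B %*% object$Tz)
}
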