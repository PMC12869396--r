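#' Fit the conical plume model to an empirical likelihood field
#'
#' Two-stage estimator.  A pilot stage recovers `(lambda, delta)` from the
#' log-log regression of the centerline detection frequency against
#' downwind distance, \eqn{\ln\ell(x, 0) = \delta\ln\lambda - \delta\ln x},
#' and `beta` from the pooled lateral Gaussian profiles (after removing
#' the per-column level, \eqn{\ln\ell} is linear in \eqn{y^2/x^2} with
#' slope \eqn{-1/\beta^2}).  A refinement stage then minimizes the
#' variance-weighted squared error on the probability scale,
#' \eqn{\sum w_i (\hat\ell_i - \ell(\phi_i; \theta))^2} with binomial
#' weights \eqn{w_i = 1/(\ell_i^0 (1 - \ell_i^0))} evaluated at the pilot
#' model.  Both the fit region (pilot prediction strictly inside
#' `(eps, 1 - eps)`, so saturated and empty cells cannot dominate) and the
#' weights come from the pilot model rather than the noisy frequencies,
#' which keeps the estimating equations unbiased under sampling noise.
#' On a noiseless field generated from the model itself the fit is exact.
#'
#' @param field A [likelihood_field()] whose centerline (row nearest
#'   `y = 0`) carries a decaying profile.
#' @param eps Saturation guard for the fit region (default 0.01).
#' @return A [plume_params()] with fitted `lambda`, `delta`, `beta` (and
#'   `c0`, `isotropic` carried over from `field$params` when present),
#'   with a `"fit"` attribute giving the pilot estimates and the number
#'   of nodes used.
#' @export
fit_conical <- function(field, eps = 0.01) {
  stopifnot(inherits(field, "likelihood_field"), eps > 0, eps < 0.5)
  xg <- field$x
  yg <- field$y
  jc <- which.min(abs(yg))

  # pilot centerline decay
  lc <- field$values[, jc]
  use <- lc > eps & lc < 1 - eps & xg > 0
  if (sum(use) < 3L)
    stop("fewer than 3 usable centerline nodes; cannot fit the decay")
  cf <- unname(stats::lm.fit(cbind(1, log(xg[use])), log(lc[use]))$coefficients)
  d0 <- -cf[2L]
  if (!is.finite(d0) || d0 <= 0)
    stop("degenerate fit: centerline profile does not decay")
  l0 <- exp(cf[1L] / d0)

  # pilot lateral width, pooled over columns after demeaning
  u_all <- z_all <- NULL
  for (i in seq_along(xg)) {
    v <- field$values[i, ]
    ok <- v > eps & v < 1 - eps
    if (sum(ok) < 3L || xg[i] <= 0) next
    u <- (yg[ok] / xg[i])^2
    if (max(u) - min(u) < .Machine$double.eps) next
    z <- log(v[ok])
    u_all <- c(u_all, u - mean(u))
    z_all <- c(z_all, z - mean(z))
  }
  if (is.null(u_all) || sum(u_all^2) <= 0)
    stop("no usable lateral profiles; cannot fit the cone half-angle")
  slope <- sum(u_all * z_all) / sum(u_all^2)
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate fit: lateral profiles do not narrow with |y|")
  b0 <- sqrt(-1 / slope)

  # refinement: binomial-weighted least squares on the probability scale
  gx <- rep(xg, times = length(yg))
  gy <- rep(yg, each = length(xg))
  obs <- as.numeric(field$values)
  model <- function(p) {
    v <- numeric(length(gx))
    pos <- gx > 0
    v[pos] <- pmin((gx[pos] / p[2L])^(-p[1L]) *
                     exp(-gy[pos]^2 / (p[3L] * gx[pos])^2), 1)
    v
  }
  pred0 <- model(c(d0, l0, b0))
  sel <- pred0 > eps & pred0 < 1 - eps
  w <- 1 / (pred0[sel] * (1 - pred0[sel]))
  obj <- function(lp) {
    p <- exp(lp)
    sum(w * (obs[sel] - model(p)[sel])^2)
  }
  o <- stats::optim(log(c(d0, l0, b0)), obj, method = "BFGS")
  p <- exp(o$par)
  if (any(!is.finite(p)))
    stop("refinement stage failed to converge")

  out <- plume_params(lambda = p[2L], delta = p[1L], beta = p[3L],
                      c0 = if (!is.null(field$params)) field$params$c0 else 1,
                      isotropic = FALSE)
  attr(out, "fit") <- list(pilot = c(delta = d0, lambda = l0, beta = b0),
                           n_centerline = sum(use), n_nodes = sum(sel))
  out
}
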