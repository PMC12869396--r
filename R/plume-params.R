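#' Parameters of the conical (or isotropic) detection-probability model
#'
#' Bundles the three parameters of the canonical anisotropic plume
#' parametrization of the odor detection probability,
#' \deqn{\ell(\phi) = (\phi_x/\lambda)^{-\delta}\,
#'       \exp(-\phi_y^2 / (\beta^2 \phi_x^2)),}
#' together with the sensitivity threshold `c0` used to binarize raw
#' concentration, and a flag selecting the isotropic (radial power-law)
#' variant used as a negative control.  All lengths are expressed in grid
#' spacings (\eqn{\Delta x}).  The defaults are the values fitted to the
#' turbulent channel-flow likelihood that the synthetic generator emulates.
#'
#' @param lambda Longitudinal decay lengthscale \eqn{\lambda > 0} (grid
#'   spacings).  Detection is certain (clamped to 1) for centerline
#'   positions closer than `lambda`.
#' @param delta Dimensionless decay exponent \eqn{\delta > 0}.
#' @param beta Dimensionless cone half-angle \eqn{\beta > 0}: the lateral
#'   Gaussian width of the plume at downwind distance \eqn{\phi_x} is
#'   \eqn{\beta\phi_x}.
#' @param c0 Concentration threshold (raw-signal units, \eqn{\ge 0}).
#' @param isotropic If `TRUE` the radial power-law variant
#'   \eqn{\min(1, (r/\lambda)^{-\delta})} is used.
#' @return An object of class `plume_params`.
#' @examples
#' p <- plume_params()
#' conical_likelihood(p, c(2 * p$lambda, 0))
#' @export
plume_params <- function(lambda = 96.86, delta = 1.54, beta = 0.08,
                         c0 = 1, isotropic = FALSE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda), lambda > 0,
            is.numeric(delta), length(delta) == 1L, is.finite(delta), delta > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0,
            is.numeric(c0), length(c0) == 1L, is.finite(c0), c0 >= 0,
            is.logical(isotropic), length(isotropic) == 1L, !is.na(isotropic))
  structure(list(lambda = lambda, delta = delta, beta = beta,
                 c0 = c0, isotropic = isotropic),
            class = "plume_params")
}

#' @export
print.plume_params <- function(x, ...) {
  kind <- if (x$isotropic) "isotropic (radial power law)" else "conical (anisotropic)"
  cat("Plume detection-probability model:", kind, "\n")
  cat(sprintf("  lambda = %.4g Dx, delta = %.4g, beta = %.4g, c0 = %.4g\n",
              x$lambda, x$delta, x$beta, x$c0))
  invisible(x)
}

# coerce phi to an n x 2 matrix of positions
as_phi_matrix <- function(phi) {
  if (is.null(dim(phi))) {
    if (length(phi) %% 2L != 0L && length(phi) != 2L)
      stop("`phi` must be a length-2 vector or an n x 2 matrix")
    phi <- matrix(phi, ncol = 2L, byrow = length(phi) == 2L)
  }
  phi <- as.matrix(phi)
  if (ncol(phi) != 2L) stop("`phi` must have two columns (x, y)")
  if (any(!is.finite(phi))) stop("non-finite position in `phi`")
  phi
}

#' Conical plume detection probability
#'
#' Evaluates the anisotropic detection-probability model at positions
#' \eqn{\phi = (\phi_x, \phi_y)} relative to the source (at the origin,
#' plume extending towards positive \eqn{\phi_x}).  Values are clamped to
#' `[0, 1]`; positions upwind of the source (\eqn{\phi_x \le 0}) have
#' probability 0.
#'
#' @param params A [plume_params()] object with `isotropic = FALSE`.
#' @param phi A length-2 vector or an n x 2 matrix of positions.
#' @return Numeric vector of detection probabilities in `[0, 1]`.
#' @export
conical_likelihood <- function(params, phi) {
  stopifnot(inherits(params, "plume_params"))
  if (params$isotropic)
    stop("`params` is isotropic; use isotropic_likelihood()")
  phi <- as_phi_matrix(phi)
  out <- numeric(nrow(phi))
  ok <- phi[, 1L] > 0
  if (any(ok)) {
    px <- phi[ok, 1L]
    py <- phi[ok, 2L]
    v <- (px / params$lambda)^(-params$delta) *
      exp(-py^2 / (params$beta^2 * px^2))
    out[ok] <- pmin(1, v)
  }
  out
}

#' Isotropic plume detection probability
#'
#' Radially symmetric control model \eqn{\min(1, (r/\lambda)^{-\delta})}
#' with \eqn{r = |\phi|}, sharing the centerline decay of the conical model
#' so that the only difference between the two is geometry.  The origin
#' (\eqn{r = 0}) is clamped to probability 1.
#'
#' @inheritParams conical_likelihood
#' @param params A [plume_params()] object with `isotropic = TRUE`.
#' @return Numeric vector of detection probabilities in `[0, 1]`.
#' @export
isotropic_likelihood <- function(params, phi) {
  stopifnot(inherits(params, "plume_params"))
  if (!params$isotropic)
    stop("`params` is anisotropic; use conical_likelihood()")
  phi <- as_phi_matrix(phi)
  r <- sqrt(phi[, 1L]^2 + phi[, 2L]^2)
  out <- numeric(nrow(phi))
  out[r == 0] <- 1
  pos <- r > 0
  out[pos] <- pmin(1, (r[pos] / params$lambda)^(-params$delta))
  out
}

#' Detection probability under either plume geometry
#'
#' Dispatches on the `isotropic` flag of `params`.
#'
#' @inheritParams conical_likelihood
#' @return Numeric vector of detection probabilities.
#' @export
plume_likelihood <- function(params, phi) {
  if (params$isotropic) isotropic_likelihood(params, phi)
  else conical_likelihood(params, phi)
}

#' Invert the centerline detection probability
#'
#' Maps a detection fraction `theta` to the centerline position whose
#' detection probability equals it, \eqn{x = \lambda\,\theta^{-1/\delta}}.
#' This is the infinite-sensor, zero-noise source-distance estimate: with
#' vanishing perceived size the Bayesian estimate is dictated entirely by
#' the detection fraction.  `theta = 0` maps to the far edge of the prior,
#' `theta >= 1` to `lambda` (or the near edge, whichever is larger); when a
#' prior is supplied the result is clamped to its x-range.
#'
#' @param params A [plume_params()] object.
#' @param theta Detection fraction(s) in `[0, 1]`.
#' @param prior Optional numeric `c(x_lo, x_hi, y_lo, y_hi)` rectangle (or
#'   a [likelihood_field()] whose prior is used) to clamp against.
#' @return Centerline position(s), grid spacings.
#' @export
invert_centerline <- function(params, theta, prior = NULL) {
  stopifnot(inherits(params, "plume_params"), all(theta >= 0 & theta <= 1))
  pr <- resolve_prior(prior)
  x <- params$lambda * ifelse(theta <= 0, Inf, theta^(-1 / params$delta))
  x <- pmax(x, params$lambda)
  if (!is.null(pr)) x <- pmin(pmax(x, pr[1L]), pr[2L])
  else x[!is.finite(x)] <- Inf
  x
}

resolve_prior <- function(prior) {
  if (is.null(prior)) return(NULL)
  if (inherits(prior, "likelihood_field")) return(prior$prior)
  stopifnot(is.numeric(prior), length(prior) == 4L,
            prior[1L] < prior[2L], prior[3L] < prior[4L])
  as.numeric(prior)
}

#' Perceived size of a multisensor agent under proprioceptive noise
#'
#' With sensors drawn uniformly in a disc of radius `R` and perceived
#' positions blurred by noise of magnitude `eta`, the effective radius of
#' the sensor cloud as seen by the estimator is approximately `R + eta`.
#'
#' @param R Agent radius (grid spacings, `>= 0`).
#' @param eta Noise magnitude (grid spacings, `>= 0`).
#' @return `R + eta`.
#' @export
perceived_size <- function(R, eta) {
  stopifnot(all(R >= 0), all(eta >= 0))
  R + eta
}
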