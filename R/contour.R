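#' Iso-probability contour of a plume as a half-width function
#'
#' For a level \eqn{L \in (0, 1)} the contour of the detection probability
#' can be written as \eqn{\phi_y = c(\phi_x)} with \eqn{c \ge 0}: the
#' lateral half-width at which the probability drops to the level.  For the
#' conical model the half-width is
#' \deqn{c(\phi_x) = \beta \phi_x \sqrt{-\delta \ln(\phi_x/\lambda) - \ln L}}
#' on its domain, with a single interior maximum at
#' \eqn{\phi_x^{peak} = \lambda L^{-1/\delta} e^{-1/2}} of height
#' \eqn{\beta \phi_x^{peak} \sqrt{\delta/2}}.  For an empirical field the
#' half-width is measured per grid column by linear interpolation and the
#' peak located by grid search.
#'
#' @param obj A [plume_params()] (anisotropic) or [likelihood_field()].
#' @param level Probability level in `(0, 1)`; must not exceed the field
#'   maximum.
#' @return An object of class `contour_function`: a list with `level`,
#'   `halfwidth` (a function of `phi_x`), `peak_x` and `peak_halfwidth`.
#' @export
contour_at_level <- function(obj, level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  UseMethod("contour_at_level")
}

#' @export
contour_at_level.plume_params <- function(obj, level) {
  if (obj$isotropic)
    stop("contour geometry is defined for the anisotropic model")
  lam <- obj$lambda; del <- obj$delta; bet <- obj$beta
  hw <- function(phi_x) {
    s <- -del * log(phi_x / lam) - log(level)
    out <- numeric(length(phi_x))
    ok <- is.finite(s) & s >= 0 & phi_x > 0
    out[ok] <- bet * phi_x[ok] * sqrt(s[ok])
    out
  }
  peak_x <- lam * level^(-1 / del) * exp(-0.5)
  structure(list(level = level, halfwidth = hw, peak_x = peak_x,
                 peak_halfwidth = bet * peak_x * sqrt(del / 2)),
            class = "contour_function")
}

#' @export
contour_at_level.likelihood_field <- function(obj, level) {
  if (level > max(obj$values))
    stop("level exceeds the field maximum")
  x <- obj$x; y <- obj$y
  jpos <- which(y >= 0)
  hw_col <- vapply(seq_along(x), function(i) {
    v <- obj$values[i, jpos]
    yy <- y[jpos]
    if (v[1L] < level) return(0)
    # outermost downcrossing of the level moving away from the centerline
    below <- which(v < level)
    if (length(below) == 0L) return(max(yy))
    k <- below[1L]
    y0 <- yy[k - 1L]; y1 <- yy[k]
    v0 <- v[k - 1L]; v1 <- v[k]
    y0 + (level - v0) / (v1 - v0) * (y1 - y0)
  }, numeric(1L))
  hw <- stats::approxfun(x, hw_col, rule = 2L)
  ipk <- which.max(hw_col)
  structure(list(level = level, halfwidth = hw, peak_x = x[ipk],
                 peak_halfwidth = hw_col[ipk]),
            class = "contour_function")
}

#' @export
print.contour_function <- function(x, ...) {
  cat(sprintf("Contour at level %.4g: peak half-width %.4g at phi_x = %.4g\n",
              x$level, x$peak_halfwidth, x$peak_x))
  invisible(x)
}
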