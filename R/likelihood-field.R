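#' Gridded detection-probability field
#'
#' A rectangular lattice of positions with a detection probability per node
#' and an axis-aligned uniform-prior rectangle for inference.  The lattice
#' is regular in each direction; `values[i, j]` is the probability at
#' `(x[i], y[j])`.
#'
#' @param x,y Strictly increasing, regularly spaced node coordinates (grid
#'   spacings).
#' @param values `length(x)` x `length(y)` matrix of probabilities in
#'   `[0, 1]`.
#' @param prior Numeric `c(x_lo, x_hi, y_lo, y_hi)`; must be contained in
#'   the grid extent.  Defaults to the full extent.
#' @param params Optional [plume_params()] the field was generated from.
#' @return An object of class `likelihood_field`.
#' @export
likelihood_field <- function(x, y, values, prior = NULL, params = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2L, length(y) >= 2L)
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(x), length(y))))
    stop("`values` must be a length(x) x length(y) matrix")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("field values must be finite probabilities in [0, 1]")
  hx <- diff(x); hy <- diff(y)
  if (any(hx <= 0) || any(hy <= 0) ||
      max(abs(hx - hx[1L])) > 1e-8 * hx[1L] ||
      max(abs(hy - hy[1L])) > 1e-8 * hy[1L])
    stop("`x` and `y` must be strictly increasing and regularly spaced")
  ext <- c(min(x), max(x), min(y), max(y))
  if (is.null(prior)) prior <- ext
  prior <- resolve_prior(prior)
  if (prior[1L] < ext[1L] - 1e-9 || prior[2L] > ext[2L] + 1e-9 ||
      prior[3L] < ext[3L] - 1e-9 || prior[4L] > ext[4L] + 1e-9)
    stop("prior rectangle must be contained in the grid extent")
  structure(list(x = as.numeric(x), y = as.numeric(y), values = values,
                 prior = prior, params = params,
                 hx = hx[1L], hy = hy[1L]),
            class = "likelihood_field")
}

#' @export
print.likelihood_field <- function(x, ...) {
  cat(sprintf("Detection-probability field: %d x %d nodes, spacing (%.3g, %.3g) Dx\n",
              length(x$x), length(x$y), x$hx, x$hy))
  cat(sprintf("  extent x [%.4g, %.4g], y [%.4g, %.4g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  prior  x [%.4g, %.4g], y [%.4g, %.4g]\n",
              x$prior[1L], x$prior[2L], x$prior[3L], x$prior[4L]))
  cat(sprintf("  values in [%.3g, %.3g]%s\n", min(x$values), max(x$values),
              if (!is.null(x$params)) " (parametric)" else " (empirical)"))
  invisible(x)
}

#' Evaluate a parametric plume on a regular grid
#'
#' Builds a [likelihood_field()] by evaluating [plume_likelihood()] on a
#' regular lattice.  The default domain follows the study geometry: the
#' prior starts at `lambda` (where the clamped conical model saturates)
#' and extends 30 decay lengths downwind; the lateral extent comfortably
#' contains the plume cone at the far edge.
#'
#' @param params A [plume_params()] object.
#' @param x_lo,x_hi Longitudinal extent (defaults `lambda`, `30 * lambda`).
#' @param y_half Lateral half-extent (default `6 * beta * lambda * 30`).
#' @param dx,dy Lattice spacings in grid-spacing units.
#' @param prior Optional prior rectangle (defaults to the full extent).
#' @return A `likelihood_field`.
#' @export
parametric_field <- function(params, x_lo = params$lambda,
                             x_hi = 30 * params$lambda,
                             y_half = 6 * params$beta * params$lambda * 30,
                             dx = 20, dy = 25, prior = NULL) {
  stopifnot(inherits(params, "plume_params"), x_hi > x_lo, y_half > 0)
  x <- seq(x_lo, x_hi, by = dx)
  ny <- 2L * ceiling(y_half / dy) + 1L
  y <- seq(-dy * (ny - 1L) / 2, dy * (ny - 1L) / 2, by = dy)
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  vals <- matrix(plume_likelihood(params, pts), nrow = length(x))
  likelihood_field(x, y, vals, prior = prior, params = params)
}

#' Empirical detection-probability field from binary snapshots
#'
#' The likelihood to detect odor at a node is estimated as the temporal
#' average of the binary measurements there, assuming statistical
#' stationarity of the odor field.
#'
#' @param snapshots A [snapshot_set] on a grid, or a 3-d array
#'   (nx x ny x time) of binary values accompanied by `x`, `y` node
#'   coordinates.
#' @param x,y Node coordinates when `snapshots` is a bare array.
#' @param prior Optional prior rectangle.
#' @return A `likelihood_field` whose values are per-node detection
#'   frequencies.
#' @export
empirical_likelihood <- function(snapshots, x = NULL, y = NULL, prior = NULL) {
  if (inherits(snapshots, "snapshot_set")) {
    if (is.null(snapshots$x))
      stop("snapshot set was sampled at points, not on a grid")
    x <- snapshots$x; y <- snapshots$y
    arr <- snapshots$binary
  } else {
    arr <- snapshots
    if (is.null(x) || is.null(y))
      stop("`x` and `y` node coordinates are required for a bare array")
  }
  if (length(dim(arr)) != 3L)
    stop("snapshots must form an nx x ny x time array")
  if (dim(arr)[1L] != length(x) || dim(arr)[2L] != length(y))
    stop("snapshot grid does not match the supplied coordinates")
  if (!all(arr %in% c(0, 1))) stop("snapshots must be binary")
  vals <- apply(arr, c(1L, 2L), mean)
  likelihood_field(x, y, vals, prior = prior)
}

# nearest-node index along one axis, clamped to the grid;
# ties at half-spacing round away from zero to match the C++ kernel
nearest_index <- function(p, x0, h, n) {
  i <- floor((p - x0) / h + 0.5) + 1
  pmin(pmax(i, 1), n)
}

#' Look up field values at positions (nearest node)
#'
#' @param field A [likelihood_field()].
#' @param phi Length-2 vector or n x 2 matrix of positions.
#' @return Numeric vector of probabilities.
#' @export
field_lookup <- function(field, phi) {
  phi <- as_phi_matrix(phi)
  i <- nearest_index(phi[, 1L], field$x[1L], field$hx, length(field$x))
  j <- nearest_index(phi[, 2L], field$y[1L], field$hy, length(field$y))
  field$values[cbind(i, j)]
}

# integer index ranges of the candidate lattice (field nodes inside the prior)
prior_index_ranges <- function(field, prior = field$prior) {
  jr <- which(field$x >= prior[1L] - 1e-9 & field$x <= prior[2L] + 1e-9)
  kr <- which(field$y >= prior[3L] - 1e-9 & field$y <= prior[4L] + 1e-9)
  if (length(jr) == 0L || length(kr) == 0L)
    stop("no candidate grid nodes inside the prior")
  list(j = range(jr), k = range(kr))
}
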