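#' Source-distance estimate from a vertically aligned detection pair
#'
#' Two detections perceived at \eqn{(x, \pm a)} pin the estimate at the
#' downwind position where the likelihood contour of half-width `a` is
#' widest: \eqn{\hat x_a = \mathrm{argmax}_{\phi_x} c_a(\phi_x)}, which
#' depends only on the perceived half-distance `a`.  For the conical model
#' the closed form is \eqn{\hat x_a = a\sqrt{2/\delta}/\beta};
#' `method = "numeric"` instead maximizes
#' \eqn{\ell(\phi_x, a)\,\ell(\phi_x, -a)} on a fine grid (the two routes
#' agree to within one grid cell).
#'
#' @param a Perceived half-distance between the detection pair (`> 0`).
#' @param obj A [plume_params()] (anisotropic) or [likelihood_field()].
#' @param method `"closed"` (parametric only) or `"numeric"`.
#' @param x_range Search range for the numeric route (defaults to the
#'   field prior, or `[lambda/10, 60 lambda]` for bare parameters).
#' @param n_grid Grid size of the numeric maximization.
#' @return An object of class `pair_estimate`: `a`, `xhat`, the contour
#'   `level` through the estimate, and the `method` tag.
#' @export
pair_estimate <- function(a, obj, method = c("closed", "numeric"),
                          x_range = NULL, n_grid = 2001L) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  method <- match.arg(method)
  if (inherits(obj, "plume_params") && method == "closed") {
    if (obj$isotropic) stop("pair geometry requires the anisotropic model")
    xhat <- a * sqrt(2 / obj$delta) / obj$beta
    level <- conical_likelihood(obj, c(xhat, a))
  } else {
    if (inherits(obj, "plume_params")) {
      if (obj$isotropic) stop("pair geometry requires the anisotropic model")
      if (is.null(x_range)) x_range <- c(obj$lambda / 10, 60 * obj$lambda)
      xs <- seq(x_range[1L], x_range[2L], length.out = n_grid)
      v <- conical_likelihood(obj, cbind(xs, a)) *
        conical_likelihood(obj, cbind(xs, -a))
    } else {
      stopifnot(inherits(obj, "likelihood_field"))
      if (a > max(obj$y))
        stop("`a` exceeds every contour half-width of the plume")
      xs <- obj$x
      v <- vapply(seq_along(xs), function(i)
        col_interp(obj, i, a) * col_interp(obj, i, -a), numeric(1L))
    }
    if (max(v) <= 0)
      stop("`a` exceeds every contour half-width of the plume")
    i <- which.max(v)
    xhat <- xs[i]
    level <- sqrt(v[i])
    method <- "numeric"
  }
  structure(list(a = a, xhat = xhat, level = level, method = method),
            class = "pair_estimate")
}

# linear interpolation of a field column's profile at lateral position y0
col_interp <- function(field, i, y0) {
  stats::approx(field$y, field$values[i, ], xout = y0, rule = 2L)$y
}

#' @export
print.pair_estimate <- function(x, ...) {
  cat(sprintf("Detection pair a = %.4g -> xhat = %.4g (%s, level %.3g)\n",
              x$a, x$xhat, x$method, x$level))
  invisible(x)
}

#' Optimal half-distance of a detection pair for a given true distance
#'
#' The half-distance \eqn{a^*} at which the pair estimate is exact,
#' \eqn{\hat x_{a^*} = x}: the maximal half-width of the likelihood
#' contour through \eqn{(x, 0)}'s widest point.  For the conical model,
#' \eqn{a^* = x\,\beta\sqrt{\delta/2}}, strictly increasing in `x`; for an
#' empirical field the contour level whose peak sits at `x` is found by
#' root-finding over levels.
#'
#' @param x True downwind distance(s) (within the representable range).
#' @param obj A [plume_params()] (anisotropic) or [likelihood_field()].
#' @return Optimal half-distance(s) `a*` (grid spacings).
#' @export
optimal_pair_distance <- function(x, obj) {
  if (inherits(obj, "plume_params")) {
    if (obj$isotropic) stop("pair geometry requires the anisotropic model")
    stopifnot(all(x > 0))
    return(x * obj$beta * sqrt(obj$delta / 2))
  }
  stopifnot(inherits(obj, "likelihood_field"))
  vmax <- min(max(obj$values), 1 - 1e-9) * 0.999
  levels <- exp(seq(log(1e-4), log(vmax), length.out = 60L))
  cts <- lapply(levels, function(L) contour_at_level(obj, L))
  pk_x <- vapply(cts, `[[`, numeric(1L), "peak_x")
  pk_h <- vapply(cts, `[[`, numeric(1L), "peak_halfwidth")
  # keep levels whose widest point is resolved inside the grid (the
  # contour neither clipped laterally nor peaking off the far edge)
  ok <- pk_h < max(obj$y) * 0.999 & pk_x < max(obj$x) - obj$hx / 2
  vapply(x, function(xi) {
    if (xi < min(obj$x) || xi > max(pk_x[ok]))
      stop("x outside the field's representable range")
    f <- function(loglev) contour_at_level(obj, exp(loglev))$peak_x - xi
    i <- which(ok & pk_x >= xi)
    j <- which(ok & pk_x <= xi)
    if (length(i) == 0L || length(j) == 0L)
      stop("x outside the field's representable range")
    lo <- log(levels[min(i)]); hi <- log(levels[max(j)])
    if (hi <= lo) return(contour_at_level(obj, exp(lo))$peak_halfwidth)
    r <- stats::uniroot(f, c(lo, hi), tol = 1e-8)
    contour_at_level(obj, exp(r$root))$peak_halfwidth
  }, numeric(1L))
}

#' Expected log-likelihood tables for the infinite-sensor estimator
#'
#' Precomputes, on a centerline candidate grid, the Gaussian-smeared
#' expected log detection (`A`) and non-detection (`B`) probabilities
#' \deqn{A(\xi_x) = E_{v \sim N(0, 1)}[\ln\ell(\xi_x, \sigma v)]}
#' via Gauss--Hermite quadrature, so that the asymptotic objective for any
#' detection fraction is the linear combination
#' \eqn{\theta A + (1 - \theta) B}.  The smear acts on the lateral
#' coordinate only: the problem is the one-dimensional centerline
#' reduction, where the perceived spread interacts with the cone geometry
#' (a longitudinal smear would merely relabel the candidate and, near the
#' source, let the narrow-cone dead zone spuriously absorb zero-detection
#' estimates).
#'
#' @param params A [plume_params()].
#' @param sigma Perceived size (`>= 0`); `sigma = 0` skips the quadrature.
#' @param prior Prior rectangle (only the x-range is used).
#' @param n_grid Number of centerline candidates.
#' @param gh_order Gauss--Hermite order (per axis, `>= 2`).
#' @param p_floor Probability floor before logs.
#' @return List with `x` (candidates), `A`, `B`, `sigma`.
#' @export
asymptotic_tables <- function(params, sigma, prior, n_grid = 801L,
                              gh_order = 32L, p_floor = 1e-6) {
  stopifnot(inherits(params, "plume_params"), sigma >= 0)
  pr <- resolve_prior(prior)
  xs <- seq(pr[1L], pr[2L], length.out = n_grid)
  clamp <- function(v) pmin(pmax(v, p_floor), 1 - p_floor)
  if (sigma == 0) {
    ell <- clamp(plume_likelihood(params, cbind(xs, 0)))
    return(list(x = xs, A = log(ell), B = log1p(-ell), sigma = sigma))
  }
  gh <- pracma::gaussHermite(gh_order)
  u <- sqrt(2) * sigma * gh$x
  w <- gh$w / sqrt(pi)
  A <- B <- numeric(n_grid)
  for (jy in seq_len(gh_order)) {
    ell <- clamp(plume_likelihood(params, cbind(xs, u[jy])))
    A <- A + w[jy] * log(ell)
    B <- B + w[jy] * log1p(-ell)
  }
  list(x = xs, A = A, B = B, sigma = sigma)
}

#' Infinite-sensor asymptotic MAP estimate on the centerline
#'
#' The estimate of an infinitely dense group of sensors with detection
#' fraction `theta` and perceived size `sigma`: the centerline position
#' maximizing the Gaussian-smeared expected log-likelihood (see
#' [asymptotic_tables()]).  With `sigma = 0` this inverts the centerline
#' likelihood (the estimate is dictated by `theta` alone); for large
#' `sigma` the estimate grows linearly in `sigma` and becomes independent
#' of `theta`, collapsing onto the detection-pair geometry.  `theta = 0`
#' returns the far edge of the prior.
#'
#' @param theta Detection fraction(s) in `[0, 1]`.
#' @param sigma Perceived size (`>= 0`).
#' @param params A [plume_params()].
#' @param prior Prior rectangle (x-range used).
#' @param tables Optional precomputed [asymptotic_tables()] for this
#'   `sigma` (then `sigma`/`params`/`prior` are ignored).
#' @inheritParams asymptotic_tables
#' With no detections at all the data carry no far-field gradient
#' information and the estimate is prior-dominated: `theta = 0` returns
#' the far edge of the prior directly (outside the far-field branch the
#' narrow cone would otherwise make the near-source off-axis region, where
#' detection is also improbable, an artefactual attractor).
#'
#' @return Estimated centerline position(s).
#' @export
asymptotic_map <- function(theta, sigma, params, prior, tables = NULL,
                           n_grid = 801L, gh_order = 32L, p_floor = 1e-6) {
  stopifnot(all(theta >= 0 & theta <= 1))
  if (is.null(tables))
    tables <- asymptotic_tables(params, sigma, prior, n_grid, gh_order, p_floor)
  far <- tables$x[length(tables$x)]
  vapply(theta, function(th) {
    if (th == 0) return(far)
    tables$x[which.max(th * tables$A + (1 - th) * tables$B)]
  }, numeric(1L))
}

#' Optimal perceived size for finite-N Bernoulli sampling
#'
#' With `N` independent sensors the detection fraction is a binomial
#' perturbation of the local likelihood; bootstrapping
#' \eqn{\hat\theta \sim \mathrm{Binomial}(N, \ell(x, 0))/N} and reading the
#' asymptotic estimate at each perceived size on a grid yields the size
#' \eqn{\sigma^*} minimizing the mean squared error to `x`.  The optimum
#' is bounded above by the optimal detection-pair half-distance
#' \eqn{a^*(x)} and shrinks to zero as `N` grows.
#'
#' @param x True centerline distance.
#' @param N Number of sensors (`>= 1`).
#' @param params A [plume_params()].
#' @param prior Prior rectangle.
#' @param sigma_grid Perceived sizes to scan (default: 0 and 20
#'   log-spaced values up to `1.5 a*(x)`).
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @param tables Optional list of precomputed [asymptotic_tables()], one
#'   per entry of `sigma_grid` (reusable across `x`).
#' @inheritParams asymptotic_tables
#' @return List with `sigma_star`, `sigma_grid`, `mse` (per size),
#'   `a_star` and the bootstrap settings.
#' @export
finite_n_optimal_sigma <- function(x, N, params, prior, sigma_grid = NULL,
                                   n_boot = 200L, seed = 1L, tables = NULL,
                                   n_grid = 801L, gh_order = 32L,
                                   p_floor = 1e-6) {
  stopifnot(N >= 1, x > 0)
  a_star <- optimal_pair_distance(x, params)
  if (is.null(sigma_grid))
    sigma_grid <- c(0, exp(seq(log(a_star / 50), log(1.5 * a_star),
                               length.out = 20L)))
  if (is.null(tables))
    tables <- lapply(sigma_grid, function(s)
      asymptotic_tables(params, s, prior, n_grid, gh_order, p_floor))
  ell0 <- plume_likelihood(params, cbind(x, 0))
  set.seed(as.integer(seed))
  th <- stats::rbinom(n_boot, N, ell0) / N
  tab_th <- table(th)
  th_u <- as.numeric(names(tab_th)); cnt <- as.numeric(tab_th)
  mse <- vapply(tables, function(tb) {
    xh <- asymptotic_map(th_u, tables = tb, sigma = tb$sigma)
    sum(cnt * (xh - x)^2) / n_boot
  }, numeric(1L))
  list(sigma_star = sigma_grid[which.min(mse)], sigma_grid = sigma_grid,
       mse = mse, a_star = a_star, N = N, n_boot = n_boot, x = x)
}

#' Empirical noise level from the current detection fraction
#'
#' A practical rule requiring no knowledge of the true distance: guess the
#' distance by inverting the centerline likelihood at the observed
#' detection fraction, then set the noise so that the perceived size
#' matches the optimal detection-pair half-distance there,
#' \eqn{\hat\eta = \max(0, a^*(x_{\hat\theta}) - R)}.
#'
#' @param theta_hat Observed detection fraction(s) in `[0, 1]`.
#' @param obj A [plume_params()] or [likelihood_field()] (a field uses its
#'   numeric centerline inversion and contour geometry).
#' @param R Agent radius.
#' @param prior Prior rectangle for clamping the distance guess (defaults
#'   to the field prior when `obj` is a field).
#' @return Empirical noise level(s) `eta_hat >= 0`.
#' @export
empirical_noise <- function(theta_hat, obj, R, prior = NULL) {
  stopifnot(all(theta_hat >= 0 & theta_hat <= 1), R >= 0)
  if (inherits(obj, "plume_params")) {
    x_guess <- invert_centerline(obj, theta_hat, prior)
    return(pmax(0, optimal_pair_distance(pmax(x_guess, 1e-9), obj) - R))
  }
  stopifnot(inherits(obj, "likelihood_field"))
  if (is.null(prior)) prior <- obj$prior
  jc <- which.min(abs(obj$y))
  prof <- obj$values[, jc]
  x_guess <- vapply(theta_hat, function(th) {
    if (th <= min(prof)) return(prior[2L])
    if (th >= max(prof)) return(max(prior[1L], obj$x[which.max(prof)]))
    # centerline profile decreases with x: invert by interpolation
    o <- order(prof)
    stats::approx(prof[o], obj$x[o], xout = th, rule = 2L)$y
  }, numeric(1L))
  x_guess <- pmin(pmax(x_guess, prior[1L]), prior[2L])
  pmax(0, optimal_pair_distance(x_guess, obj) - R)
}
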