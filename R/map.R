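#' Maximum-a-posteriori source-center estimate on the field lattice
#'
#' Maximizes the log-posterior
#' \deqn{\sum_i m_i \ln\ell(\xi + \delta_i) +
#'       (1 - m_i)\ln(1 - \ell(\xi + \delta_i))}
#' over candidate centers \eqn{\xi} on the field lattice restricted to the
#' prior rectangle, where \eqn{\delta_i} are the perceived sensor offsets
#' and the uniform prior contributes only its support.  Probabilities are
#' clamped to `[p_floor, 1 - p_floor]` before taking logs; per-sensor
#' positions are read at the nearest lattice node (clamped to the grid
#' edge); ties break deterministically towards the smallest x, then the
#' smallest y.
#'
#' @param obs An [observation()].
#' @param field A [likelihood_field()].
#' @param p_floor Probability floor before logs (default `1e-6`).
#' @param prior Prior rectangle (defaults to `field$prior`).
#' @param tables Optional precomputed (possibly error-corrected) log
#'   tables from [field_log_tables()]/[corrected_log_tables()].
#' @param keep_surface If `TRUE`, attach the full log-posterior surface.
#' @return An object of class `map_estimate`: `xhat`, `yhat`, `theta_hat`,
#'   `n_detections`, lattice indices `j`, `k`, log-posterior `value`, and
#'   (optionally) `surface` with its candidate coordinates.
#' @export
map_estimate <- function(obs, field, p_floor = 1e-6, prior = field$prior,
                         tables = NULL, keep_surface = FALSE) {
  stopifnot(inherits(obs, "observation"), inherits(field, "likelihood_field"))
  if (is.null(tables)) tables <- field_log_tables(field, p_floor)
  sh <- offset_shifts(obs$perceived, field)
  rg <- prior_index_ranges(field, resolve_prior(prior))
  res <- grid_map_cpp(tables$logA, tables$logB, obs$detections,
                      sh$sx, sh$sy,
                      rg$j[1L] - 1L, rg$j[2L] - 1L,
                      rg$k[1L] - 1L, rg$k[2L] - 1L)
  out <- list(xhat = field$x[res$j], yhat = field$y[res$k],
              theta_hat = obs$theta_hat,
              n_detections = sum(obs$detections),
              j = res$j, k = res$k, value = res$value)
  if (keep_surface) {
    out$surface <- res$logpost
    out$surface_x <- field$x[rg$j[1L]:rg$j[2L]]
    out$surface_y <- field$y[rg$k[1L]:rg$k[2L]]
  }
  structure(out, class = "map_estimate")
}

#' @export
print.map_estimate <- function(x, ...) {
  cat(sprintf("MAP estimate: (%.4g, %.4g), %d detections (theta_hat %.3f)\n",
              x$xhat, x$yhat, x$n_detections, x$theta_hat))
  invisible(x)
}

# integer lattice shifts of the perceived offsets (nearest-node rule)
offset_shifts <- function(perceived, field) {
  list(sx = as.integer(floor(perceived[, 1L] / field$hx + 0.5)),
       sy = as.integer(floor(perceived[, 2L] / field$hy + 0.5)))
}

#' Error-corrected log-likelihood tables
#'
#' When the agent knows the magnitude `eta0` of its own noise it can fold
#' the noise into the per-sensor detection model before maximizing:
#'
#' * `"flip"`: the detection probability becomes
#'   \eqn{\ell' = \eta_0 + (1 - 2\eta_0)\ell} (fixed point at 0.5);
#'   \eqn{\eta_0 \ge 0.5} is non-identifiable and raises an error.
#' * `"proprioceptive"` / `"positional"`: the field is replaced by its
#'   expectation under the truncated-Gaussian blur,
#'   \eqn{\bar\ell(\phi) = E_\gamma[\ell(\phi + \gamma)]}, computed by
#'   separable discrete convolution on the lattice (edge-renormalized).
#' * `"raw"`: with the two-point raw proxy (background 0, burst level
#'   \eqn{2 c_0}), \eqn{\ell' = \ell\,\Phi(c_0/\eta_0) +
#'   (1 - \ell)\,\Phi(-c_0/\eta_0)} — an approximation consistent with the
#'   synthetic raw construction.
#'
#' `eta0 = 0` returns the uncorrected tables.
#'
#' @param field A [likelihood_field()].
#' @param noise A [noise_spec()] whose `eta` is the known noise level.
#' @param p_floor Probability floor before logs.
#' @return A list with `logA`, `logB` as in [field_log_tables()].
#' @export
corrected_log_tables <- function(field, noise, p_floor = 1e-6) {
  stopifnot(inherits(field, "likelihood_field"), inherits(noise, "noise_spec"))
  eta <- noise$eta
  if (eta == 0) return(field_log_tables(field, p_floor))
  v <- switch(noise$mechanism,
    flip = {
      if (eta >= 0.5) stop("flip correction with eta0 >= 0.5 is non-identifiable")
      eta + (1 - 2 * eta) * field$values
    },
    proprioceptive = ,
    positional = smooth_truncgauss(field$values, field$hx, field$hy, eta),
    raw = {
      c0 <- field_c0(field)
      field$values * stats::pnorm(c0 / eta) +
        (1 - field$values) * stats::pnorm(-c0 / eta)
    },
    stop("unknown noise mechanism"))
  vc <- pmin(pmax(v, p_floor), 1 - p_floor)
  list(logA = log(vc), logB = log1p(-vc))
}

#' Log tables for the uncorrected field
#'
#' @inheritParams corrected_log_tables
#' @return A list with `logA = log(l)`, `logB = log(1 - l)` after clamping
#'   to `[p_floor, 1 - p_floor]`.
#' @export
field_log_tables <- function(field, p_floor = 1e-6) {
  v <- pmin(pmax(field$values, p_floor), 1 - p_floor)
  list(logA = log(v), logB = log1p(-v))
}

# separable discrete convolution with the truncated-normal blur kernel,
# renormalized at the grid edges
smooth_truncgauss <- function(values, hx, hy, eta) {
  smooth1 <- function(mat, h) {
    K <- floor((eta + 1) / h)
    if (K < 1L) return(mat)
    off <- (-K):K
    w <- stats::dnorm(off * h, sd = eta)
    w <- w / sum(w)
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wsum <- numeric(n)
    for (ii in seq_along(off)) {
      idx <- seq_len(n) + off[ii]
      ok <- idx >= 1L & idx <= n
      out[ok, ] <- out[ok, ] + w[ii] * mat[idx[ok], ]
      wsum[ok] <- wsum[ok] + w[ii]
    }
    out / wsum
  }
  t(smooth1(t(smooth1(values, hx)), hy))
}

#' Convenience wrapper: MAP estimate with error correction
#'
#' @inheritParams map_estimate
#' @param noise A [noise_spec()] with the known noise level `eta0`.
#' @return A `map_estimate`.
#' @export
corrected_map_estimate <- function(obs, field, noise, p_floor = 1e-6,
                                   prior = field$prior, keep_surface = FALSE) {
  map_estimate(obs, field, p_floor = p_floor, prior = prior,
               tables = corrected_log_tables(field, noise, p_floor),
               keep_surface = keep_surface)
}

#' MAP estimate from a single-sensor time series
#'
#' Multiplies the per-time Bernoulli likelihoods of a single (fixed,
#' possibly strided) sensor over the prior lattice: with uncorrelated
#' samples this is the temporal analogue of the multisensor estimate.
#'
#' @param series Binary detection series \eqn{m_t}.
#' @param offset Length-2 sensor offset relative to the candidate center.
#' @param field A [likelihood_field()].
#' @param dt_stride Keep every `dt_stride`-th sample (default 1); with
#'   temporally correlated data a stride well beyond the correlation time
#'   makes the retained samples effectively independent.
#' @inheritParams map_estimate
#' @return A `map_estimate` (its `n_detections` counts the retained
#'   samples' detections).
#' @export
single_sensor_timeseries_map <- function(series, offset, field, dt_stride = 1L,
                                         p_floor = 1e-6, prior = field$prior) {
  stopifnot(length(series) >= 1L, all(series %in% c(0, 1)), dt_stride >= 1L)
  keep <- series[seq(1L, length(series), by = dt_stride)]
  obs <- observation(keep,
                     matrix(rep(as.numeric(offset), each = length(keep)),
                            ncol = 2L))
  map_estimate(obs, field, p_floor = p_floor, prior = prior)
}
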