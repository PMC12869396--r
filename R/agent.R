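#' Place sensors uniformly inside a disc
#'
#' Draws `N` sensor offsets independently and area-uniformly inside the
#' disc of radius `R` (radius as `R * sqrt(u)`, angle uniform) around the
#' agent center.  Perceived offsets default to the real offsets (perfect
#' proprioception).
#'
#' @param center Agent center `(x, y)` in grid spacings.
#' @param R Agent radius (`> 0`).
#' @param N Number of sensors (`>= 1`).
#' @param seed Integer seed.
#' @return An object of class `agent_geometry`: `center`, `R`, `n_sensors`,
#'   `offsets` (N x 2 real offsets) and `perceived` (N x 2).
#' @export
place_sensors <- function(center, R, N, seed) {
  stopifnot(length(center) == 2L, R > 0, N >= 1)
  set.seed(as.integer(seed))
  u <- stats::runif(2L * N)
  geom <- agent_geometry(center, R, disc_offsets(u, R, N))
  geom
}

# area-uniform disc offsets from 2N uniforms (radius block, then angle block)
disc_offsets <- function(u, R, N) {
  r <- R * sqrt(u[seq_len(N)])
  a <- 2 * pi * u[N + seq_len(N)]
  cbind(r * cos(a), r * sin(a))
}

agent_geometry <- function(center, R, offsets, perceived = offsets) {
  offsets <- as.matrix(offsets); perceived <- as.matrix(perceived)
  stopifnot(ncol(offsets) == 2L, nrow(perceived) == nrow(offsets))
  if (any(sqrt(rowSums(offsets^2)) > R + 1e-9))
    stop("real sensor offsets must lie inside the disc of radius R")
  structure(list(center = as.numeric(center), R = R,
                 n_sensors = nrow(offsets),
                 offsets = offsets, perceived = perceived),
            class = "agent_geometry")
}

#' @export
print.agent_geometry <- function(x, ...) {
  cat(sprintf("Agent: %d sensors in a disc of radius %.3g Dx at (%.4g, %.4g)\n",
              x$n_sensors, x$R, x$center[1L], x$center[2L]))
  invisible(x)
}

# inverse-CDF of the zero-mean truncated normal (sd eta, bounds +/-(eta+1));
# shared with the runner so common random numbers couple draws across eta
trunc_gauss_quantile <- function(u, eta) {
  if (eta == 0) return(numeric(length(u)) * u)  # zeros, NA-propagating
  b <- (eta + 1) / eta
  pl <- stats::pnorm(-b)
  eta * stats::qnorm(pl + u * (1 - 2 * pl))
}

#' Truncated-Gaussian positional noise
#'
#' Draws per-coordinate noise from a zero-mean Gaussian with standard
#' deviation `eta` truncated to `[-(eta + 1), eta + 1]` (so the blur can
#' never exceed the perceived size by more than one grid spacing);
#' `eta = 0` returns exact zeros.
#'
#' @param eta Noise magnitude (grid spacings, `>= 0`).
#' @param count Number of 2-d offsets to draw.
#' @param seed Integer seed.
#' @return `count` x 2 matrix of noise offsets.
#' @export
truncated_gaussian_noise <- function(eta, count, seed) {
  stopifnot(eta >= 0, count >= 0)
  set.seed(as.integer(seed))
  u <- stats::runif(2L * count)
  matrix(trunc_gauss_quantile(u, eta), ncol = 2L)
}

#' Noise mechanism specification
#'
#' The four ways noise enters the pipeline: `"proprioceptive"` blurs the
#' perceived sensor positions only (processing, not input);
#' `"positional"` blurs the real positions at which sensors sample while
#' the estimator keeps the nominal offsets; `"flip"` swaps each binary
#' detection with probability `eta`; `"raw"` adds Gaussian noise of
#' standard deviation `eta` to the raw concentration before thresholding.
#' `eta` is a length for the positional mechanisms, a probability
#' (`<= 0.5`) for `"flip"` and in raw-signal units for `"raw"`.
#'
#' @param mechanism One of `"proprioceptive"`, `"positional"`, `"flip"`,
#'   `"raw"`.
#' @param eta Noise magnitude (`>= 0`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mechanism = c("proprioceptive", "positional",
                                     "flip", "raw"),
                       eta = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta), eta >= 0)
  if (mechanism == "flip" && eta > 0.5)
    stop("flip probability eta must not exceed 0.5")
  structure(list(mechanism = mechanism, eta = eta), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise: %s, eta = %.4g\n", x$mechanism, x$eta))
  invisible(x)
}

#' Per-sensor observation
#'
#' @param detections Binary vector of per-sensor detections.
#' @param perceived N x 2 matrix of perceived sensor offsets (relative to
#'   the unknown center) used by the estimator.
#' @return An object of class `observation` with `detections`, `perceived`
#'   and `theta_hat = mean(detections)`.
#' @export
observation <- function(detections, perceived) {
  perceived <- as.matrix(perceived)
  stopifnot(all(detections %in% c(0, 1)),
            nrow(perceived) == length(detections), ncol(perceived) == 2L)
  structure(list(detections = as.integer(detections), perceived = perceived,
                 theta_hat = mean(detections)),
            class = "observation")
}

#' @export
print.observation <- function(x, ...) {
  cat(sprintf("Observation: %d/%d detections (theta_hat = %.3f)\n",
              sum(x$detections), length(x$detections), x$theta_hat))
  invisible(x)
}

# read a gridded snapshot at absolute positions (nearest node, time t)
read_snapshot <- function(snap, positions, t = 1L, what = c("binary", "raw")) {
  what <- match.arg(what)
  arr <- snap[[what]]
  if (is.null(arr)) stop("snapshot set has no ", what, " values")
  if (is.null(snap$x)) stop("snapshot set was sampled at points; ",
                            "positions cannot be re-read")
  positions <- as_phi_matrix(positions)
  i <- nearest_index(positions[, 1L], snap$x[1L], snap$x[2L] - snap$x[1L],
                     length(snap$x))
  j <- nearest_index(positions[, 2L], snap$y[1L], snap$y[2L] - snap$y[1L],
                     length(snap$y))
  arr[cbind(i, j, t)]
}

#' Apply a noise mechanism to one snapshot readout
#'
#' Produces the [observation()] an agent would pass to the estimator:
#' `"proprioceptive"` reads detections at the real sensor positions and
#' blurs only the perceived offsets; `"positional"` reads at blurred real
#' positions while reporting the nominal offsets; `"flip"` flips each
#' detection independently with probability `eta`; `"raw"` perturbs the
#' raw concentration with Gaussian noise before thresholding at `c0`.
#' With `eta = 0` every mechanism reduces to the noiseless readout.
#'
#' @param geometry An [place_sensors()] geometry.
#' @param noise A [noise_spec()].
#' @param snapshot A gridded `snapshot_set` covering all sensor positions
#'   (with raw values for the `"raw"` mechanism).
#' @param seed Integer seed for the noise draws.
#' @param t Time index of the snapshot to read.
#' @param c0 Threshold for the `"raw"` mechanism (defaults to 1).
#' @return An [observation()].
#' @export
apply_noise <- function(geometry, noise, snapshot, seed, t = 1L, c0 = 1) {
  stopifnot(inherits(geometry, "agent_geometry"), inherits(noise, "noise_spec"))
  set.seed(as.integer(seed))
  N <- geometry$n_sensors
  pos_real <- sweep(geometry$offsets, 2L, geometry$center, "+")
  eta <- noise$eta
  switch(noise$mechanism,
    proprioceptive = {
      m <- read_snapshot(snapshot, pos_real, t)
      gam <- matrix(trunc_gauss_quantile(stats::runif(2L * N), eta), ncol = 2L)
      observation(m, geometry$offsets + gam)
    },
    positional = {
      gam <- matrix(trunc_gauss_quantile(stats::runif(2L * N), eta), ncol = 2L)
      m <- read_snapshot(snapshot, pos_real + gam, t)
      observation(m, geometry$offsets)
    },
    flip = {
      m <- read_snapshot(snapshot, pos_real, t)
      rho <- stats::runif(N) < eta
      observation((m + rho) %% 2L, geometry$offsets)
    },
    raw = {
      cr <- read_snapshot(snapshot, pos_real, t, what = "raw")
      ct <- cr + eta * stats::rnorm(N)
      observation(binarize(ct, c0), geometry$offsets)
    },
    stop("unknown noise mechanism"))
}
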