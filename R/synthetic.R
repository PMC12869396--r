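#' Spatiotemporal correlation specification for surrogate odor snapshots
#'
#' Describes the latent-Gaussian correlation structure used by
#' [sample_correlated()].  `corr_length = 0` and `corr_time = 0` reduce to
#' independent Bernoulli sampling.
#'
#' @param corr_length Spatial correlation length of the latent field
#'   (grid spacings, `>= 0`).
#' @param corr_time Temporal correlation of the latent field, in snapshot
#'   intervals (`>= 0`); the latent field follows an AR(1) process with
#'   autocorrelation `exp(-1 / corr_time)` per interval.
#' @param kernel Spatial covariance family; only `"squared-exponential"`
#'   (\eqn{k(d) = \exp(-d^2 / 2 l^2)}) is provided.
#' @return An object of class `correlation_spec`.
#' @export
correlation_spec <- function(corr_length = 0, corr_time = 0,
                             kernel = "squared-exponential") {
  stopifnot(is.numeric(corr_length), length(corr_length) == 1L, corr_length >= 0,
            is.numeric(corr_time), length(corr_time) == 1L, corr_time >= 0)
  kernel <- match.arg(kernel, "squared-exponential")
  structure(list(corr_length = corr_length, corr_time = corr_time,
                 kernel = kernel),
            class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat(sprintf("Correlation spec: %s kernel, length %.3g Dx, time %.3g intervals\n",
              x$kernel, x$corr_length, x$corr_time))
  invisible(x)
}

# Cholesky factor (upper) of the spatial kernel with a small nugget
kernel_chol <- function(d2, corr_length) {
  K <- exp(-d2 / (2 * corr_length^2))
  diag(K) <- diag(K) + 1e-8
  U <- tryCatch(chol(K), error = function(e)
    stop("kernel configuration is not positive definite: ",
         conditionMessage(e)))
  U
}

# standard-normal upper quantile at probability ell (detect iff g >= z)
upper_quantile <- function(ell) stats::qnorm(1 - ell)

ell_at_points <- function(field, pts) {
  if (!is.null(field$params)) plume_likelihood(field$params, pts)
  else field_lookup(field, pts)
}

#' Sample independent Bernoulli odor snapshots
#'
#' Each node (or point) and time index is an independent Bernoulli draw
#' with the local detection probability.  Equivalent to
#' [sample_correlated()] with zero correlation length and time.
#'
#' @param field A [likelihood_field()] supplying the marginal detection
#'   probabilities (a parametric field is evaluated exactly at points).
#' @param n_snapshots Number of snapshots (`>= 1`).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param points Optional n x 2 matrix of sampling positions; when `NULL`
#'   the full field grid is sampled.
#' @param raw If `TRUE`, also return the positive raw-concentration proxy
#'   from [raw_from_latent()].
#' @param raw_scale Log-scale `s` of the raw proxy.
#' @return A `snapshot_set`.
#' @export
sample_bernoulli <- function(field, n_snapshots, seed, points = NULL,
                             raw = FALSE, raw_scale = 1) {
  sample_correlated(field, correlation_spec(0, 0), n_snapshots, seed,
                    points = points, raw = raw, raw_scale = raw_scale)
}

#' Sample spatiotemporally correlated binary odor snapshots
#'
#' Surrogate for turbulent odor data: a latent zero-mean unit-variance
#' Gaussian field with squared-exponential spatial covariance and AR(1)
#' temporal correlation is thresholded at the standard-normal upper
#' quantile of the local detection probability, so every node's long-run
#' detection frequency equals the target likelihood exactly (Gaussian
#' copula), while nearby nodes and consecutive snapshots are positively
#' correlated with tunable decay.
#'
#' On the full grid the separability of the squared-exponential kernel is
#' exploited (matrix-normal sampling via the two 1-D Cholesky factors); at
#' arbitrary points the full pairwise kernel is factored.
#'
#' @inheritParams sample_bernoulli
#' @param corr A [correlation_spec()].
#' @return An object of class `snapshot_set`: grid coordinates (or
#'   `points`), a binary array (nx x ny x time on the grid, n x time at
#'   points), the latent field, optionally raw values, the seed and the
#'   correlation spec used.
#' @export
sample_correlated <- function(field, corr, n_snapshots, seed, points = NULL,
                              raw = FALSE, raw_scale = 1) {
  stopifnot(inherits(field, "likelihood_field"),
            inherits(corr, "correlation_spec"),
            n_snapshots >= 1)
  n_snapshots <- as.integer(n_snapshots)
  rho <- if (corr$corr_time > 0) exp(-1 / corr$corr_time) else 0
  set.seed(as.integer(seed))
  if (is.null(points)) {
    nx <- length(field$x); ny <- length(field$y)
    if (corr$corr_length > 0) {
      Ux <- kernel_chol(outer(field$x, field$x, function(a, b) (a - b)^2),
                        corr$corr_length)
      Uy <- kernel_chol(outer(field$y, field$y, function(a, b) (a - b)^2),
                        corr$corr_length)
    }
    draw <- function() {
      Z <- matrix(stats::rnorm(nx * ny), nx, ny)
      if (corr$corr_length > 0) crossprod(Ux, Z) %*% Uy else Z
    }
    g <- array(NA_real_, c(nx, ny, n_snapshots))
    g[, , 1L] <- draw()
    if (n_snapshots > 1L) for (t in 2L:n_snapshots)
      g[, , t] <- rho * g[, , t - 1L] + sqrt(1 - rho^2) * draw()
    z <- upper_quantile(field$values)
    m <- array(0L, dim(g))
    for (t in seq_len(n_snapshots)) m[, , t] <- (g[, , t] >= z) + 0L
    out <- list(x = field$x, y = field$y, points = NULL,
                binary = m, latent = g)
  } else {
    points <- as_phi_matrix(points)
    n <- nrow(points)
    ell <- ell_at_points(field, points)
    z <- upper_quantile(ell)
    if (corr$corr_length > 0) {
      d2 <- as.matrix(stats::dist(points))^2
      U <- kernel_chol(d2, corr$corr_length)
    }
    draw <- function() {
      zv <- stats::rnorm(n)
      if (corr$corr_length > 0) as.numeric(crossprod(U, zv)) else zv
    }
    g <- matrix(NA_real_, n, n_snapshots)
    g[, 1L] <- draw()
    if (n_snapshots > 1L) for (t in 2L:n_snapshots)
      g[, t] <- rho * g[, t - 1L] + sqrt(1 - rho^2) * draw()
    m <- (g >= z) + 0L
    out <- list(x = NULL, y = NULL, points = points, binary = m, latent = g)
  }
  out$raw <- if (raw) raw_from_latent(out$latent, field, field_c0(field),
                                      raw_scale, points = points) else NULL
  out$seed <- as.integer(seed)
  out$corr <- corr
  class(out) <- "snapshot_set"
  out
}

field_c0 <- function(field) {
  if (!is.null(field$params)) field$params$c0 else 1
}

#' @export
print.snapshot_set <- function(x, ...) {
  where <- if (is.null(x$points))
    sprintf("%d x %d grid", length(x$x), length(x$y))
  else sprintf("%d points", nrow(x$points))
  nt <- utils::tail(dim(x$binary), 1L)
  cat(sprintf("Snapshot set: %s, %d snapshots, seed %d\n", where, nt, x$seed))
  print(x$corr)
  invisible(x)
}

#' Raw concentration proxy from the latent Gaussian field
#'
#' Builds positive, log-normal-style raw concentrations
#' \eqn{c = c_0 \exp(s (g - z(\phi)))} from the latent field `g` and the
#' local threshold quantile \eqn{z(\phi)}, so that `c >= c0` exactly when
#' the thresholded binary value is 1 (mimicking intermittent odor bursts).
#' At nodes with detection probability exactly 0 or 1 the proxy degenerates
#' to 0 or `Inf`, preserving the thresholding identity.
#'
#' @param latent Latent Gaussian values, shaped as in the `snapshot_set`.
#' @param field The [likelihood_field()] supplying the marginals.
#' @param c0 Concentration threshold (`> 0` for a nondegenerate proxy).
#' @param scale Log-scale `s > 0`.
#' @param points Points matrix when the latent was sampled at points.
#' @return Raw values with the shape of `latent`.
#' @export
raw_from_latent <- function(latent, field, c0 = field_c0(field), scale = 1,
                            points = NULL) {
  stopifnot(scale > 0, c0 >= 0)
  if (is.null(points)) {
    z <- upper_quantile(field$values)
    if (length(dim(latent)) == 3L) {
      out <- latent
      for (t in seq_len(dim(latent)[3L]))
        out[, , t] <- c0 * exp(scale * (latent[, , t] - z))
      return(out)
    }
    return(c0 * exp(scale * (latent - z)))
  }
  z <- upper_quantile(ell_at_points(field, points))
  out <- c0 * exp(scale * sweep(as.matrix(latent), 1L, z))
  if (is.null(dim(latent))) as.numeric(out) else out
}

#' Threshold raw concentrations into binary detections
#'
#' A sensor reports 1 exactly when the raw concentration reaches its
#' sensitivity threshold: `raw >= c0` (inclusive).
#'
#' @param raw Raw concentration values (any shape).
#' @param c0 Sensitivity threshold.
#' @return Integer 0/1 values with the shape of `raw`.
#' @export
binarize <- function(raw, c0) {
  out <- (raw >= c0) + 0L
  dim(out) <- dim(raw)
  out
}
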