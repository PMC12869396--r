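#' Default rectangular grid of test locations
#'
#' Agent centers arranged as `n_x` downwind stations spanning
#' `[0.1, 0.95]` of the domain length by `n_y` rows symmetric about the
#' centerline.
#'
#' @param field A [likelihood_field()] (its prior sets the domain).
#' @param n_x,n_y Grid dimensions (defaults 31 x 5).
#' @param y_step Row spacing (grid spacings).
#' @return Data frame with columns `loc_id`, `x`, `y`.
#' @export
default_test_grid <- function(field, n_x = 31L, n_y = 5L, y_step = 50) {
  L <- field$prior[2L]
  xs <- seq(0.1 * L, 0.95 * L, length.out = n_x)
  ys <- y_step * (seq_len(n_y) - (n_y + 1L) / 2)
  g <- expand.grid(x = xs, y = ys)
  data.frame(loc_id = seq_len(nrow(g)), x = g$x, y = g$y)
}

#' Scenario configuration
#'
#' Validates and bundles everything one inference experiment needs; a
#' scenario is fully reproducible from its configuration and the master
#' seed.
#'
#' @param field A [likelihood_field()] (the model used for inference and,
#'   through its marginals, for data generation).
#' @param truth Data frame of test locations (`loc_id`, `x`, `y`);
#'   defaults to a scaled-down 9 x 3 grid.
#' @param N Sensors per agent.
#' @param R Agent radius.
#' @param mechanism Noise mechanism (see [noise_spec()]).
#' @param eta Noise level(s): a numeric vector (scanned with common
#'   random numbers) or `"empirical"` for detection-fraction-driven
#'   tuning of proprioceptive noise.
#' @param corrected If `TRUE`, inference uses the error-corrected
#'   likelihood for the (single, known) `eta`.
#' @param sampling `"bernoulli"` (independent detections) or
#'   `"correlated"` (latent Gaussian surrogate).
#' @param corr A [correlation_spec()] for `sampling = "correlated"`;
#'   defaults to correlation length `R/2` (odor patches below the agent
#'   scale, so detection counts are graded rather than all-or-nothing)
#'   and correlation time 5.
#' @param Nr Realizations per location.
#' @param master_seed Integer master seed; per-(location, realization)
#'   sub-seeds are derived by a fixed hash so that compared conditions
#'   share random numbers.
#' @param exclude_min_detections Realizations with fewer detections are
#'   flagged excluded (default 2; set 0 to disable).
#' @param p_floor Probability floor for the MAP search.
#' @param raw_scale Log-scale of the raw concentration proxy (default 0.1,
#'   keeping an appreciable fraction of readings near the sensitivity
#'   threshold as in intermittent odor signals).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(field, truth = NULL, N = 500L, R = 25,
                            mechanism = "proprioceptive", eta = 0,
                            corrected = FALSE,
                            sampling = c("correlated", "bernoulli"),
                            corr = NULL, Nr = 30L, master_seed = 1L,
                            exclude_min_detections = 2L, p_floor = 1e-6,
                            raw_scale = 0.1) {
  stopifnot(inherits(field, "likelihood_field"), N >= 1, R > 0, Nr >= 1)
  sampling <- match.arg(sampling)
  mechanism <- match.arg(mechanism,
                         c("proprioceptive", "positional", "flip", "raw"))
  empirical <- identical(eta, "empirical")
  if (empirical) {
    if (mechanism != "proprioceptive")
      stop("empirical tuning is defined for proprioceptive noise")
    if (corrected) stop("empirical tuning cannot be combined with correction")
    eta <- NA_real_
  } else {
    stopifnot(is.numeric(eta), all(is.finite(eta)), all(eta >= 0))
    if (mechanism == "flip" && any(eta > 0.5))
      stop("flip probability eta must not exceed 0.5 ",
           "(eta is a probability for this mechanism)")
    if (corrected && length(eta) != 1L)
      stop("corrected inference requires a single known eta")
  }
  if (is.null(truth)) truth <- default_test_grid(field, n_x = 9L, n_y = 3L)
  stopifnot(all(c("loc_id", "x", "y") %in% names(truth)))
  if (is.null(corr)) corr <- correlation_spec(corr_length = R / 2, corr_time = 5)
  structure(list(field = field, truth = truth, N = as.integer(N), R = R,
                 mechanism = mechanism, eta = eta, empirical = empirical,
                 corrected = corrected, sampling = sampling, corr = corr,
                 Nr = as.integer(Nr), master_seed = as.integer(master_seed),
                 exclude_min_detections = as.integer(exclude_min_detections),
                 p_floor = p_floor, raw_scale = raw_scale),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %s sampling, %s noise (eta %s%s), N = %d, R = %.3g\n",
              x$sampling, x$mechanism,
              if (x$empirical) "empirical"
              else paste(signif(x$eta, 3), collapse = "/"),
              if (x$corrected) ", corrected" else "",
              x$N, x$R))
  cat(sprintf("  %d locations x %d realizations, master seed %d\n",
              nrow(x$truth), x$Nr, x$master_seed))
  invisible(x)
}

# deterministic sub-seed per (location, realization); independent of the
# noise level and mechanism so compared conditions share random numbers
sub_seed <- function(master, loc, rep) {
  s <- master %% 1000003
  s <- (s * 1009 + loc) %% 1000003
  s <- (s * 1009 + rep) %% 1000003
  as.integer(s + 1)
}

# fast empirical-noise rule: closed forms when the field is parametric,
# otherwise a precomputed interpolation of the field's contour geometry
make_empirical_noise_fn <- function(config) {
  field <- config$field; R <- config$R; prior <- field$prior
  if (!is.null(field$params)) {
    params <- field$params
    return(function(theta_hat) empirical_noise(theta_hat, params, R, prior))
  }
  th_grid <- seq(0.001, 0.999, length.out = 200L)
  eta_grid <- empirical_noise(th_grid, field, R, prior)
  function(theta_hat)
    stats::approx(th_grid, eta_grid, xout = theta_hat, rule = 2L)$y
}

#' Run one inference scenario
#'
#' For every test location and realization: place sensors, draw one odor
#' snapshot at the sensors (independent Bernoulli or the correlated
#' Gaussian-copula surrogate), apply the configured noise mechanism at
#' every requested level (reusing the same base random draws across
#' levels), run the grid MAP estimate (error-corrected when requested),
#' and flag realizations below the minimum-detections rule.  Inference is
#' instantaneous: one snapshot per realization.
#'
#' @param config A [scenario_config()].
#' @return A list with `records` (one row per realization and noise
#'   level: truth, estimate, mechanism, eta, theta_hat, n_detections,
#'   seed, excluded) and `metrics` (per-location [mse_bias()] for each
#'   eta).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  field <- config$field
  N <- config$N; R <- config$R; Nr <- config$Nr
  mech <- config$mechanism
  etas <- if (config$empirical) NA_real_ else config$eta
  n_eta <- length(etas)
  correlated <- config$sampling == "correlated" && config$corr$corr_length > 0
  c0 <- field_c0(field)
  tables <- if (config$corrected)
    corrected_log_tables(field, noise_spec(mech, config$eta), config$p_floor)
  else field_log_tables(field, config$p_floor)
  emp_fn <- if (config$empirical) make_empirical_noise_fn(config)
  truth <- config$truth
  n_loc <- nrow(truth)
  n_rows <- n_loc * Nr * n_eta
  col_loc <- col_rep <- col_nd <- col_seed <- integer(n_rows)
  col_x <- col_y <- col_eta <- col_xh <- col_yh <- col_th <- numeric(n_rows)
  col_ex <- logical(n_rows)
  ri <- 0L
  for (il in seq_len(n_loc)) {
    center <- c(truth$x[il], truth$y[il])
    for (rep_i in seq_len(Nr)) {
      sd_i <- sub_seed(config$master_seed, truth$loc_id[il], rep_i)
      set.seed(sd_i)
      u_off <- stats::runif(2L * N)
      z_lat <- stats::rnorm(N)
      u_flip <- stats::runif(N)
      z_raw <- stats::rnorm(N)
      u_gam <- stats::runif(2L * N)
      offsets <- disc_offsets(u_off, R, N)
      pos_real <- sweep(offsets, 2L, center, "+")
      ell <- ell_at_points(field, pos_real)
      z_th <- upper_quantile(ell)
      g <- if (correlated) {
        U <- kernel_chol(as.matrix(stats::dist(pos_real))^2,
                         config$corr$corr_length)
        as.numeric(crossprod(U, z_lat))
      } else z_lat
      m0 <- as.integer(g >= z_th)
      for (ie in seq_len(n_eta)) {
        eta <- etas[ie]
        if (config$empirical) eta <- emp_fn(mean(m0))
        if (mech == "proprioceptive" || config$empirical) {
          gam <- matrix(trunc_gauss_quantile(u_gam, eta), ncol = 2L)
          obs <- observation(m0, offsets + gam)
        } else if (mech == "positional") {
          gam <- matrix(trunc_gauss_quantile(u_gam, eta), ncol = 2L)
          pos2 <- pos_real + gam
          ell2 <- ell_at_points(field, pos2)
          g2 <- if (correlated) {
            U2 <- kernel_chol(as.matrix(stats::dist(pos2))^2,
                              config$corr$corr_length)
            as.numeric(crossprod(U2, z_lat))
          } else z_lat
          obs <- observation(as.integer(g2 >= upper_quantile(ell2)), offsets)
        } else if (mech == "flip") {
          obs <- observation((m0 + (u_flip < eta)) %% 2L, offsets)
        } else {
          craw <- c0 * exp(config$raw_scale * (g - z_th))
          obs <- observation(as.integer(craw + eta * z_raw >= c0), offsets)
        }
        est <- map_estimate(obs, field, p_floor = config$p_floor,
                            tables = tables)
        ri <- ri + 1L
        col_loc[ri] <- truth$loc_id[il]
        col_x[ri] <- center[1L]; col_y[ri] <- center[2L]
        col_rep[ri] <- rep_i; col_eta[ri] <- eta
        col_xh[ri] <- est$xhat; col_yh[ri] <- est$yhat
        col_th[ri] <- obs$theta_hat; col_nd[ri] <- est$n_detections
        col_ex[ri] <- est$n_detections < config$exclude_min_detections
        col_seed[ri] <- sd_i
      }
    }
  }
  records <- data.frame(loc_id = col_loc, x = col_x, y = col_y,
                        rep = col_rep, mechanism = mech, eta = col_eta,
                        xhat = col_xh, yhat = col_yh, theta_hat = col_th,
                        n_detections = col_nd, excluded = col_ex,
                        seed = col_seed)
  metrics <- if (config$empirical || n_eta == 1L) mse_bias(records)
  else do.call(rbind, lapply(split(records, records$eta), mse_bias))
  list(records = records, metrics = metrics, config = config)
}

#' Per-location mean squared error and bias
#'
#' \eqn{MSE_x = \frac1{N_r}\sum_i (\hat x_i - x)^2} and
#' \eqn{b_x = \frac1{N_r}\sum_i (\hat x_i - x)} over the non-excluded
#' realizations at each location (and likewise for y).  Locations whose
#' realizations were all excluded are flagged `missing`.  The attribute
#' `"var_x_prior"` (when a prior is supplied) carries the uniform-prior
#' variance \eqn{(x_{hi} - x_{lo})^2 / 12} used for normalized reporting.
#'
#' @param records A record data frame from [run_scenario()] (or of the
#'   same shape).
#' @param use_exclusion If `FALSE`, excluded realizations re-enter the
#'   averages.
#' @param prior Optional prior rectangle for the normalization attribute.
#' @return Data frame with one row per location: `loc_id`, `x`, `y`,
#'   `eta`, `MSEx`, `MSEy`, `bx`, `by`, `n_used`, `n_excluded`,
#'   `missing`.
#' @export
mse_bias <- function(records, use_exclusion = TRUE, prior = NULL) {
  stopifnot(all(c("loc_id", "x", "y", "xhat", "yhat") %in% names(records)))
  out <- do.call(rbind, lapply(split(records, records$loc_id), function(rr) {
    keep <- if (use_exclusion && "excluded" %in% names(rr)) !rr$excluded
    else rep(TRUE, nrow(rr))
    n_used <- sum(keep)
    base <- data.frame(loc_id = rr$loc_id[1L], x = rr$x[1L], y = rr$y[1L],
                       eta = if ("eta" %in% names(rr)) rr$eta[1L] else NA_real_,
                       n_used = n_used, n_excluded = nrow(rr) - n_used,
                       missing = n_used == 0L)
    if (n_used == 0L) {
      base$MSEx <- base$MSEy <- base$bx <- base$by <- NA_real_
    } else {
      ex <- rr$xhat[keep] - rr$x[keep]
      ey <- rr$yhat[keep] - rr$y[keep]
      base$MSEx <- mean(ex^2); base$MSEy <- mean(ey^2)
      base$bx <- mean(ex); base$by <- mean(ey)
    }
    base[, c("loc_id", "x", "y", "eta", "MSEx", "MSEy", "bx", "by",
             "n_used", "n_excluded", "missing")]
  }))
  rownames(out) <- NULL
  pr <- resolve_prior(prior)
  if (!is.null(pr)) attr(out, "var_x_prior") <- (pr[2L] - pr[1L])^2 / 12
  out
}

#' Aggregate squared errors into close / mid / far regions
#'
#' Splits the downwind stations into three regions — for the canonical
#' 31-column grid, 11/10/10 columns (55/50/50 locations over 5 rows);
#' any other layout falls back to x-terciles — and returns box statistics
#' of the per-realization squared errors in x per region.
#'
#' @param records A record data frame (non-excluded rows are used when an
#'   `excluded` column is present).
#' @return Data frame with one row per region: `region`, `n_loc`, `n`,
#'   `median`, `q25`, `q75` of the squared error, and `mse`.
#' @export
region_aggregate <- function(records) {
  keep <- if ("excluded" %in% names(records)) !records$excluded
  else rep(TRUE, nrow(records))
  rr <- records[keep, , drop = FALSE]
  xs <- sort(unique(records$x))
  ncol_x <- length(xs)
  sizes <- if (ncol_x == 31L) c(11L, 10L, 10L)
  else diff(round(seq(0, ncol_x, length.out = 4L)))
  bounds <- cumsum(sizes)
  region_of <- function(x) {
    i <- match(x, xs)
    c("close", "mid", "far")[findInterval(i, c(0, bounds), left.open = TRUE,
                                          rightmost.closed = TRUE)]
  }
  rr$region <- factor(region_of(rr$x), levels = c("close", "mid", "far"))
  loc_region <- factor(region_of(records$x), levels = levels(rr$region))
  se <- (rr$xhat - rr$x)^2
  out <- do.call(rbind, lapply(levels(rr$region), function(g) {
    s <- se[rr$region == g]
    if (length(s) == 0L)
      return(data.frame(region = g, n_loc = 0L, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, mse = NA_real_))
    data.frame(region = g,
               n_loc = length(unique(records$loc_id[loc_region == g])),
               n = length(s),
               median = stats::median(s),
               q25 = unname(stats::quantile(s, 0.25)),
               q75 = unname(stats::quantile(s, 0.75)),
               mse = mean(s))
  }))
  rownames(out) <- NULL
  out
}

#' Uniform-random baseline estimates
#'
#' The reference estimator that ignores the data: estimates drawn
#' uniformly over the prior rectangle.  As the number of realizations
#' grows its \eqn{MSE_x} tends to
#' \eqn{\mathrm{Var}(x_{prior}) + (x - E[x_{prior}])^2}.
#'
#' @param prior Prior rectangle `c(x_lo, x_hi, y_lo, y_hi)` (or a
#'   [likelihood_field()]).
#' @param truth Data frame of test locations (`loc_id`, `x`, `y`).
#' @param Nr Realizations per location.
#' @param seed Integer seed.
#' @return A record data frame compatible with [mse_bias()].
#' @export
random_baseline <- function(prior, truth, Nr, seed) {
  pr <- resolve_prior(prior)
  set.seed(as.integer(seed))
  n <- nrow(truth) * Nr
  data.frame(loc_id = rep(truth$loc_id, each = Nr),
             x = rep(truth$x, each = Nr), y = rep(truth$y, each = Nr),
             rep = rep(seq_len(Nr), times = nrow(truth)),
             mechanism = "random", eta = NA_real_,
             xhat = stats::runif(n, pr[1L], pr[2L]),
             yhat = stats::runif(n, pr[3L], pr[4L]),
             theta_hat = NA_real_, n_detections = NA_integer_,
             excluded = FALSE, seed = as.integer(seed))
}

#' Scan the noise level and locate the optimum per location
#'
#' Runs the full inference at every level of `eta_grid` with common
#' random numbers, returns the per-location tuning curve
#' \eqn{MSE_x(\eta)}, the optimal level \eqn{\eta^*} (ties towards the
#' smallest level), and the optimal perceived size
#' \eqn{\sigma^* = R + \eta^*}.
#'
#' @param config A [scenario_config()] (its `eta` is ignored).
#' @param eta_grid Noise levels to scan; must include 0.  Default: 0 and
#'   15 log-spaced values from `R/10` to `10 R`.
#' @return A list of class `tuning_scan`: `curve` (per location x eta),
#'   `optimum` (per location: `eta_star`, `sigma_star`, `mse_star`,
#'   `mse_zero`, `a_star` when the field is parametric), `records`.
#' @export
optimal_noise_scan <- function(config, eta_grid = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(eta_grid))
    eta_grid <- c(0, config$R * 10^seq(-1, 1, length.out = 15L))
  stopifnot(any(eta_grid == 0))
  eta_grid <- sort(unique(eta_grid))
  config$eta <- eta_grid
  config$empirical <- FALSE
  res <- run_scenario(config)
  curve <- res$metrics
  opt <- do.call(rbind, lapply(split(curve, curve$loc_id), function(cc) {
    cc <- cc[order(cc$eta), ]
    ok <- !cc$missing
    if (!any(ok))
      return(data.frame(loc_id = cc$loc_id[1L], x = cc$x[1L], y = cc$y[1L],
                        eta_star = NA_real_, sigma_star = NA_real_,
                        mse_star = NA_real_, mse_zero = NA_real_))
    i <- which.min(cc$MSEx[ok])
    io <- which(ok)[i]
    data.frame(loc_id = cc$loc_id[1L], x = cc$x[1L], y = cc$y[1L],
               eta_star = cc$eta[io], sigma_star = config$R + cc$eta[io],
               mse_star = cc$MSEx[io],
               mse_zero = cc$MSEx[cc$eta == 0])
  }))
  rownames(opt) <- NULL
  if (!is.null(config$field$params) && !config$field$params$isotropic)
    opt$a_star <- optimal_pair_distance(opt$x, config$field$params)
  structure(list(curve = curve, optimum = opt, records = res$records,
                 config = config),
            class = "tuning_scan")
}

#' @export
print.tuning_scan <- function(x, ...) {
  cat(sprintf("Noise scan: %d locations x %d eta levels (%s noise)\n",
              nrow(x$optimum), length(unique(x$curve$eta)),
              x$config$mechanism))
  print(utils::head(x$optimum, 10L))
  invisible(x)
}

#' Compare aggregate error statistics across conditions
#'
#' Pools the per-location \eqn{MSE_x} of several metric tables sharing
#' the same test grid into one summary of box statistics.  Statistics are
#' computed over the locations that are non-missing in *every* condition,
#' so conditions that rescue otherwise-empty locations (for example,
#' flipping noise at detection-free sites) are compared like for like.
#'
#' @param ... Named metric tables from [mse_bias()] (or one named list).
#' @return Data frame with one row per condition: `condition`, `n_loc`,
#'   `median_MSEx`, `q25`, `q75`, `mean_MSEx`.
#' @export
compare_conditions <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !is.data.frame(tabs[[1L]])) tabs <- tabs[[1L]]
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    stop("conditions must be named")
  key <- function(tb) paste(sort(unique(tb$loc_id)), collapse = ",")
  keys <- vapply(tabs, key, character(1L))
  if (length(unique(keys)) != 1L)
    stop("conditions must share the same test grid")
  common <- Reduce(intersect, lapply(tabs, function(tb) tb$loc_id[!tb$missing]))
  if (length(common) == 0L) stop("no location is non-missing in every condition")
  out <- do.call(rbind, lapply(names(tabs), function(nm) {
    tb <- tabs[[nm]]
    v <- tb$MSEx[tb$loc_id %in% common]
    data.frame(condition = nm, n_loc = length(v),
               median_MSEx = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               mean_MSEx = mean(v))
  }))
  rownames(out) <- NULL
  out
}
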