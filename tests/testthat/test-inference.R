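test_that("sensor placement is area-uniform in the disc", {
  g <- place_sensors(c(0, 0), R = 30, N = 1e5, seed = 1)
  r <- sqrt(rowSums(g$offsets^2))
  expect_true(all(r <= 30))
  expect_equal(mean(r), 2 * 30 / 3, tolerance = 0.01)   # uniform-disc moment
  expect_equal(g$perceived, g$offsets)
  g1 <- place_sensors(c(5, 5), R = 2, N = 1, seed = 3)
  expect_equal(nrow(g1$offsets), 1L)
})

test_that("truncated Gaussian noise matches its closed-form moments and bounds", {
  expect_true(all(truncated_gaussian_noise(0, 100, seed = 1) == 0))
  eta <- 25
  gam <- truncated_gaussian_noise(eta, 1e5, seed = 2)
  expect_true(all(abs(gam) <= eta + 1))
  a <- (eta + 1) / eta    # standardized truncation bound
  sd_true <- eta * sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
  expect_equal(sd(as.numeric(gam)), sd_true, tolerance = 0.01)
})

test_that("noise mechanisms act on the advertised part of the pipeline", {
  p <- fit_params()
  f <- small_field(p)
  snap <- sample_correlated(f, correlation_spec(20, 0), 1, seed = 5, raw = TRUE)
  geom <- place_sensors(c(500, 0), 25, 50, seed = 6)
  base <- apply_noise(geom, noise_spec("proprioceptive", 0), snap, seed = 7)
  for (mech in c("proprioceptive", "positional", "flip", "raw")) {
    o <- apply_noise(geom, noise_spec(mech, 0), snap, seed = 7,
                     c0 = field_c0(f))
    expect_identical(o$detections, base$detections, label = mech)
    expect_equal(o$perceived, geom$offsets, label = mech)
  }
  # proprioceptive noise perturbs processing only, never the readout
  o <- apply_noise(geom, noise_spec("proprioceptive", 40), snap, seed = 8)
  expect_identical(o$detections, base$detections)
  expect_false(identical(o$perceived, geom$offsets))
  # flipping all-ones detections at 0.5 halves the detection fraction
  ones <- constant_field(1)
  snap1 <- sample_bernoulli(ones, 1, seed = 1)
  geom1 <- place_sensors(c(30, 0), 10, 400, seed = 2)
  th <- mean(sapply(1:20, function(s)
    apply_noise(geom1, noise_spec("flip", 0.5), snap1, seed = s)$theta_hat))
  expect_equal(th, 0.5, tolerance = 0.03)
  expect_error(noise_spec("flip", 0.7), "0.5")
})

test_that("grid MAP matches monotone-field intuition at the extremes", {
  p <- fit_params()
  f <- small_field(p)
  # one detecting sensor at the center: the posterior peaks at the
  # near-source prior corner on the centerline (negative detection bias)
  o1 <- observation(1L, matrix(0, 1, 2))
  e1 <- map_estimate(o1, f)
  expect_equal(e1$xhat, f$prior[1])
  expect_equal(e1$yhat, 0)
  # all sensors silent, centerline prior: the estimate collapses to the
  # furthest point (the monotone far-field limit of the decay)
  o0 <- observation(rep(0L, 20), matrix(rnorm(40, sd = 5), 20, 2))
  e0 <- map_estimate(o0, f, prior = c(f$prior[1], f$prior[2], -1, 1))
  expect_equal(e0$xhat, f$prior[2])
})

test_that("compiled MAP search equals the brute-force posterior oracle", {
  set.seed(99)
  p <- fit_params()
  f <- parametric_field(p, x_hi = 8 * p$lambda, y_half = 150, dx = 60, dy = 50)
  for (i in 1:10) {
    N <- sample(3:25, 1)
    m <- rbinom(N, 1, 0.4)
    perc <- cbind(rnorm(N, sd = 40), rnorm(N, sd = 40))
    obs <- observation(m, perc)
    fast <- map_estimate(obs, f, keep_surface = TRUE)
    slow <- brute_map(obs, f)
    expect_identical(c(fast$xhat, fast$yhat), c(slow$xhat, slow$yhat))
  }
})

test_that("MAP estimate is invariant to sensor order and equivariant to translation", {
  set.seed(7)
  p <- fit_params()
  f <- small_field(p)
  m <- rbinom(12, 1, 0.5)
  perc <- cbind(rnorm(12, sd = 30), rnorm(12, sd = 30))
  e <- map_estimate(observation(m, perc), f)
  idx <- sample(12)
  e2 <- map_estimate(observation(m[idx], perc[idx, ]), f)
  expect_identical(c(e$xhat, e$yhat), c(e2$xhat, e2$yhat))
  # shift the whole problem by one lattice vector
  shift <- c(2 * f$hx, -1 * f$hy)
  f2 <- likelihood_field(f$x + shift[1], f$y + shift[2], f$values,
                         prior = f$prior + shift[c(1, 1, 2, 2)],
                         params = f$params)
  e3 <- map_estimate(observation(m, perc), f2)
  expect_equal(c(e3$xhat, e3$yhat), c(e$xhat, e$yhat) + shift)
})

test_that("error-corrected likelihoods obey their limits and formulas", {
  p <- fit_params()
  f <- small_field(p)
  base <- field_log_tables(f)
  for (mech in c("proprioceptive", "positional", "flip", "raw")) {
    tb <- corrected_log_tables(f, noise_spec(mech, 0))
    expect_identical(tb, base, label = mech)
  }
  # flip correction formula and its fixed point at one half
  tb <- corrected_log_tables(f, noise_spec("flip", 0.01))
  expect_equal(exp(tb$logA[f$values == max(f$values)][1]),
               0.01 + 0.98 * max(f$values), tolerance = 1e-9)
  ellp <- 0.01 + (1 - 2 * 0.01) * 0.5
  expect_equal(ellp, 0.5)
  expect_error(corrected_log_tables(f, noise_spec("flip", 0.5)),
               "non-identifiable")
  # positional smoothing with a blur far below the lattice spacing is a no-op
  tb2 <- corrected_log_tables(f, noise_spec("positional", 1))
  expect_equal(tb2$logA, base$logA, tolerance = 1e-12)
  # wide smoothing preserves probability mass away from the edges
  tb3 <- corrected_log_tables(f, noise_spec("positional", 60))
  expect_true(all(is.finite(tb3$logA)))
  expect_lt(max(exp(tb3$logA)), 1)
  # raw correction mixes the burst and background exceedance probabilities
  tb4 <- corrected_log_tables(f, noise_spec("raw", 0.5))
  i <- which.max(f$values)
  expect_equal(exp(tb4$logA)[i],
               f$values[i] * pnorm(1 / 0.5) + (1 - f$values[i]) * pnorm(-1 / 0.5),
               tolerance = 1e-6)
})

test_that("single-sensor time series inference sharpens with independent samples", {
  p <- fit_params()
  f <- parametric_field(p, x_hi = 8 * p$lambda, y_half = 150, dx = 25, dy = 30)
  # one time point reduces to the one-sensor instantaneous estimate
  e1 <- single_sensor_timeseries_map(1L, c(0, 0), f)
  e2 <- map_estimate(observation(1L, matrix(0, 1, 2)), f)
  expect_identical(c(e1$xhat, e1$yhat), c(e2$xhat, e2$yhat))

  x0 <- 400
  ct <- 3   # latent correlation time, in snapshot intervals
  mse_for <- function(nt, stride, nrep, corr_time) {
    errs <- sapply(seq_len(nrep), function(r) {
      s <- sample_correlated(f, correlation_spec(0, corr_time),
                             n_snapshots = nt * stride, seed = 3000 + r,
                             points = cbind(x0, 0))
      # temporal correlation only: reuse the latent path at one point
      est <- single_sensor_timeseries_map(as.integer(s$binary[1, ]),
                                          c(0, 0), f, dt_stride = stride)
      est$xhat - x0
    })
    mean(errs^2)
  }
  m_s1 <- mse_for(20, 1, 150, ct)
  m_s9 <- mse_for(20, 9, 150, ct)
  m_boot <- mse_for(20, 1, 150, 0)   # independent samples, same NT
  # striding past the correlation time recovers the independent accuracy
  expect_gt(m_s1, m_s9)
  expect_lt(abs(m_s9 - m_boot), 0.6 * m_boot)
  # more independent time points keep improving the estimate
  m_nt5 <- mse_for(5, 9, 150, ct)
  expect_gt(m_nt5, m_s9)
})

test_that("perceived size adds the noise magnitude to the radius", {
  expect_equal(perceived_size(25, 0), 25)
  expect_equal(perceived_size(25, 25), 50)
  expect_equal(perceived_size(10, 74), 84)
})
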