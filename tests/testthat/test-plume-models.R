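test_that("conical likelihood matches closed-form values and conventions", {
  p <- fit_params()
  # on the decay lengthscale the centerline value saturates at 1
  expect_equal(conical_likelihood(p, c(96.86, 0)), 1)
  # pure centerline decay: (2)^-delta
  expect_equal(conical_likelihood(p, c(193.72, 0)), 2^(-1.54))
  # one lateral e-folding at phi_y = beta * phi_x
  expect_equal(conical_likelihood(p, c(193.72, 0.08 * 193.72)),
               2^(-1.54) * exp(-1))
  # upwind convention and input checks
  expect_equal(conical_likelihood(p, c(-10, 0)), 0)
  expect_equal(conical_likelihood(p, c(0, 5)), 0)
  expect_error(conical_likelihood(p, c(NaN, 0)), "non-finite")
  expect_error(conical_likelihood(plume_params(isotropic = TRUE), c(100, 0)),
               "isotropic")
})

test_that("conical likelihood is monotone along and across the plume", {
  set.seed(11)
  for (rep in 1:5) {
    p <- plume_params(lambda = runif(1, 20, 200), delta = runif(1, 0.5, 3),
                      beta = runif(1, 0.02, 0.3))
    xs <- seq(p$lambda, 40 * p$lambda, length.out = 200)
    v <- conical_likelihood(p, cbind(xs, 0))
    expect_true(all(diff(v) <= 1e-12))
    x0 <- 5 * p$lambda
    ys <- seq(0, 3 * p$beta * x0, length.out = 100)
    vy <- conical_likelihood(p, cbind(x0, ys))
    expect_true(all(diff(vy) <= 1e-12))
  }
})

test_that("isotropic likelihood is rotation invariant and clamps at the source", {
  p <- plume_params(isotropic = TRUE)
  expect_equal(isotropic_likelihood(p, c(0, 96.86)), 1)
  expect_equal(isotropic_likelihood(p, c(137, 137)),
               (sqrt(2) * 137 / 96.86)^(-1.54), tolerance = 1e-10)
  expect_equal(isotropic_likelihood(p, c(0, 0)), 1)
  set.seed(3)
  r <- 350; ang <- runif(8, 0, 2 * pi)
  v <- isotropic_likelihood(p, cbind(r * cos(ang), r * sin(ang)))
  expect_true(max(v) - min(v) < 1e-12)
})

test_that("centerline inversion is the inverse of the centerline decay", {
  p <- fit_params()
  expect_equal(invert_centerline(p, 1), 96.86)
  expect_equal(invert_centerline(p, 0.344), 193.7, tolerance = 1e-3)
  f <- parametric_field(p)
  expect_equal(invert_centerline(p, 0, prior = f$prior), f$prior[2])
  # round trip on the centerline between lambda and the far edge
  xs <- seq(p$lambda, f$prior[2], length.out = 25)
  th <- conical_likelihood(p, cbind(xs, 0))
  expect_equal(invert_centerline(p, th, prior = f$prior), xs, tolerance = 1e-8)
})

test_that("empirical likelihood averages binary snapshots per node", {
  f <- constant_field(0.5)
  ones <- array(1L, c(6, 5, 3))
  expect_true(all(empirical_likelihood(ones, x = f$x, y = f$y)$values == 1))
  two <- array(c(rep(0L, 30), rep(1L, 30)), c(6, 5, 2))
  expect_true(all(empirical_likelihood(two, x = f$x, y = f$y)$values == 0.5))
  expect_error(empirical_likelihood(array(0.3, c(6, 5, 2)), x = f$x, y = f$y),
               "binary")
  # binomial concentration: node means of many Bernoulli snapshots sit
  # within 3 standard errors of the generating field at >= 99% of nodes
  p <- fit_params()
  gen <- parametric_field(p, x_hi = 8 * p$lambda, y_half = 120, dx = 60, dy = 40)
  snaps <- sample_bernoulli(gen, n_snapshots = 10000, seed = 77)
  emp <- empirical_likelihood(snaps)
  tol <- 3 * sqrt(gen$values * (1 - gen$values) / 10000)
  frac_ok <- mean(abs(emp$values - gen$values) <= pmax(tol, 1e-12))
  expect_gte(frac_ok, 0.99)
})

test_that("conical fit recovers noiseless generators exactly and rejects flat fields", {
  p <- fit_params()
  f <- parametric_field(p, x_hi = 10 * p$lambda, y_half = 200, dx = 25, dy = 20)
  fit <- fit_conical(f)
  expect_equal(fit$lambda, p$lambda, tolerance = 1e-3)
  expect_equal(fit$delta, p$delta, tolerance = 1e-3)
  expect_equal(fit$beta, p$beta, tolerance = 1e-3)
  # refit idempotence: a field generated from the fit reproduces the fit
  f2 <- parametric_field(fit, x_hi = 10 * fit$lambda, y_half = 200,
                         dx = 25, dy = 20)
  fit2 <- fit_conical(f2)
  expect_equal(fit2$delta, fit$delta, tolerance = 1e-3)
  expect_error(fit_conical(constant_field(0.5)), "decay|usable")
})

test_that("contour geometry matches the closed form and brute-force search", {
  p <- fit_params()
  # level chosen so the contour peaks at x = 500
  L0 <- (500 * exp(0.5) / p$lambda)^(-p$delta)
  cf <- contour_at_level(p, L0)
  expect_equal(cf$peak_x, 500, tolerance = 1e-9)
  expect_equal(cf$peak_halfwidth, 500 * 0.08 * sqrt(1.54 / 2), tolerance = 1e-9)
  expect_equal(cf$peak_halfwidth, cf$halfwidth(cf$peak_x), tolerance = 1e-9)
  # numeric contour of a gridded field agrees within one grid cell
  f <- parametric_field(p, x_hi = 12 * p$lambda, y_half = 150, dx = 5, dy = 2)
  for (lev in c(0.15, 0.3, 0.5)) {
    ca <- contour_at_level(p, lev)
    cn <- contour_at_level(f, lev)
    expect_lt(abs(cn$peak_x - ca$peak_x), f$hx + 1e-9)
    expect_lt(abs(cn$peak_halfwidth - ca$peak_halfwidth), f$hy + 1e-9)
  }
  expect_error(contour_at_level(constant_field(0.2), 0.5), "maximum")
})

test_that("field, parameter and record files round-trip through text", {
  p <- plume_params(lambda = 50, delta = 2, beta = 0.1, c0 = 2)
  f <- parametric_field(p, x_hi = 5 * 50, y_half = 60, dx = 25, dy = 20)
  tmp <- tempfile(fileext = ".txt")
  write_field(f, tmp)
  f2 <- read_field(tmp)
  expect_equal(f2$values, f$values, tolerance = 1e-12)
  expect_equal(f2$x, f$x); expect_equal(f2$prior, f$prior)
  expect_equal(f2$params$delta, 2)
  tmp2 <- tempfile(fileext = ".cfg")
  write_params(p, tmp2)
  expect_equal(read_params(tmp2), p)
  rec <- random_baseline(f, data.frame(loc_id = 1:2, x = c(100, 200), y = 0),
                         Nr = 3, seed = 5)
  tmp3 <- tempfile(fileext = ".tsv")
  write_records(rec, tmp3)
  expect_equal(read_records(tmp3)$xhat, rec$xhat, tolerance = 1e-12)
})
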