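test_that("per-location error metrics match direct computation", {
  rec <- data.frame(loc_id = 1, x = 10, y = 0, rep = 1:2,
                    xhat = c(11, 9), yhat = c(0, 0), excluded = FALSE)
  m <- mse_bias(rec)
  expect_equal(m$MSEx, 1); expect_equal(m$bx, 0)
  rec2 <- rec; rec2$xhat <- rec2$x; rec2$yhat <- rec2$y
  m2 <- mse_bias(rec2)
  expect_equal(c(m2$MSEx, m2$MSEy, m2$bx, m2$by), c(0, 0, 0, 0))
  # 5-record fixture against a spreadsheet-style recomputation
  xh <- c(12, 7, 15, 10, 6); yh <- c(1, -2, 0, 3, -1)
  rec3 <- data.frame(loc_id = 2, x = 10, y = 0, rep = 1:5,
                     xhat = xh, yhat = yh, excluded = FALSE)
  m3 <- mse_bias(rec3)
  expect_equal(m3$MSEx, sum((xh - 10)^2) / 5)
  expect_equal(m3$bx, sum(xh - 10) / 5)
  expect_equal(m3$MSEy, sum(yh^2) / 5)
  # variance decomposition invariant on random records
  set.seed(2)
  rec4 <- data.frame(loc_id = rep(1:4, each = 20), x = rep(c(5, 10, 20, 40), each = 20),
                     y = 0, rep = 1:20,
                     xhat = runif(80, 0, 50), yhat = rnorm(80), excluded = FALSE)
  m4 <- mse_bias(rec4)
  expect_true(all(m4$MSEx >= m4$bx^2 - 1e-12))
  expect_true(all(m4$MSEy >= m4$by^2 - 1e-12))
})

test_that("regional aggregation splits the canonical grid 55/50/50", {
  xs <- seq(100, 3100, length.out = 31)
  g <- expand.grid(x = xs, y = c(-2, -1, 0, 1, 2))
  rec <- data.frame(loc_id = seq_len(nrow(g)), x = g$x, y = g$y, rep = 1,
                    xhat = g$x + rnorm(nrow(g)), yhat = g$y, excluded = FALSE)
  ra <- region_aggregate(rec)
  expect_equal(ra$region, c("close", "mid", "far"))
  expect_equal(ra$n_loc, c(55, 50, 50))
  # medians match direct sorting within each region
  close_se <- (rec$xhat[rec$x <= xs[11]] - rec$x[rec$x <= xs[11]])^2
  expect_equal(ra$median[1], median(close_se))
  # non-canonical layouts fall back to x-terciles
  rec9 <- rec[rec$x %in% xs[1:9], ]
  expect_equal(region_aggregate(rec9)$n_loc, c(15, 15, 15))
  # degenerate single-column grid: all points end up in one region
  rec1 <- rec[rec$x == xs[1], ]
  ra1 <- region_aggregate(rec1)
  expect_equal(sum(ra1$n, na.rm = TRUE), nrow(rec1))
  expect_equal(sum(ra1$n > 0), 1)
})

test_that("random baseline has uniform-prior moments and stays inside", {
  prior <- c(100, 2900, -500, 500)
  truth <- data.frame(loc_id = 1, x = 800, y = 0)
  rec <- random_baseline(prior, truth, Nr = 20000, seed = 11)
  expect_true(all(rec$xhat >= 100 & rec$xhat <= 2900))
  expect_true(all(rec$yhat >= -500 & rec$yhat <= 500))
  varx <- (2900 - 100)^2 / 12
  expect_equal(mse_bias(rec)$MSEx, varx + (800 - 1500)^2, tolerance = 0.02)
  expect_identical(random_baseline(prior, truth, 5, seed = 3)$xhat,
                   random_baseline(prior, truth, 5, seed = 3)$xhat)
})

test_that("scenario runs are bit-identical under a fixed master seed", {
  p <- fit_params()
  f <- small_field(p)
  truth <- data.frame(loc_id = 1:2, x = c(400, 900), y = c(0, 50))
  cfg <- scenario_config(f, truth, N = 50, R = 25, Nr = 3, master_seed = 77,
                         eta = c(0, 30))
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$records, b$records)
  c <- run_scenario(scenario_config(f, truth, N = 50, R = 25, Nr = 3,
                                    master_seed = 78, eta = c(0, 30)))
  expect_false(identical(a$records$xhat, c$records$xhat))
})

test_that("the exclusion rule is accounted for and toggleable", {
  p <- fit_params()
  f <- small_field(p)
  truth <- data.frame(loc_id = 1, x = 1300, y = 0)   # sparse detections
  cfg <- scenario_config(f, truth, N = 20, R = 25, Nr = 40, master_seed = 5,
                         sampling = "correlated")
  res <- run_scenario(cfg)
  m_excl <- mse_bias(res$records)
  expect_gt(m_excl$n_excluded, 0)
  m_all <- mse_bias(res$records, use_exclusion = FALSE)
  expect_equal(m_all$n_used, 40)
  expect_false(isTRUE(all.equal(m_excl$MSEx, m_all$MSEx)))
})

test_that("accuracy improves with the number of sensors under perfect information", {
  p <- fit_params()
  f <- parametric_field(p, y_half = 600, dx = 25, dy = 30)
  truth <- data.frame(loc_id = 1:2, x = c(400, 700), y = 0)
  msex <- sapply(c(10, 100, 500), function(N) {
    cfg <- scenario_config(f, truth, N = N, R = 25, Nr = 40, master_seed = 9,
                           sampling = "bernoulli", eta = 0,
                           exclude_min_detections = 0L)
    mean(mse_bias(run_scenario(cfg)$records)$MSEx)
  })
  expect_true(all(diff(msex) <= 0))
  expect_lt(msex[3], msex[1])
})

test_that("flipping noise does not help independent isotropic sampling", {
  pI <- plume_params(isotropic = TRUE)
  f <- parametric_field(pI, y_half = 600, dx = 25, dy = 30)
  truth <- data.frame(loc_id = 1:3, x = c(400, 900, 1400), y = 0)
  cfg <- scenario_config(f, truth, N = 10, R = 25, Nr = 120, master_seed = 31,
                         sampling = "bernoulli", mechanism = "flip",
                         eta = c(0, 0.001, 0.01, 0.05))
  res <- run_scenario(cfg)
  rec0 <- res$records[res$records$eta == 0, ]
  for (e in c(0.001, 0.01, 0.05)) {
    d <- paired_se_diff(rec0, res$records[res$records$eta == e, ])
    # MSE(0) - MSE(eta) must not be significantly positive
    expect_lte(d$mean, 2 * d$se + 1e-9)
  }
})

test_that("condition summaries are reproducible and grid-checked", {
  set.seed(4)
  mk <- function() {
    rec <- data.frame(loc_id = rep(1:6, each = 5), x = rep(c(1:6) * 100, each = 5),
                      y = 0, rep = 1:5, xhat = runif(30, 0, 600), yhat = 0,
                      excluded = FALSE)
    mse_bias(rec)
  }
  a <- mk()
  s1 <- compare_conditions(one = a, two = a)
  expect_equal(s1$median_MSEx[1], s1$median_MSEx[2])
  b <- mk(); b <- b[b$loc_id < 6, ]
  expect_error(compare_conditions(one = a, two = b), "grid")
  expect_error(compare_conditions(a, b), "named")
})
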