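# Shared fixtures and independent oracles for the test suite.

# canonical anisotropic parameters used throughout
fit_params <- function() plume_params()

# small parametric field, cheap enough for brute-force work
small_field <- function(params = fit_params(), dx = 40, dy = 50,
                        x_hi = 15 * params$lambda, y_half = 400) {
  parametric_field(params, x_hi = x_hi, y_half = y_half, dx = dx, dy = dy)
}

# constant-probability field on a small grid
constant_field <- function(p, nx = 6L, ny = 5L, h = 10) {
  likelihood_field(x = h * seq_len(nx), y = h * (seq_len(ny) - 3L),
                   values = matrix(p, nx, ny))
}

# Brute-force MAP oracle: direct per-candidate evaluation of the
# log-posterior in plain R, independent of the compiled kernel.  Shares
# only the stated contracts (nearest-node reads, edge clamping, probability
# floor, ties to smallest x then y).
brute_map <- function(obs, field, p_floor = 1e-6, prior = field$prior) {
  v <- pmin(pmax(field$values, p_floor), 1 - p_floor)
  logA <- log(v); logB <- log(1 - v)
  nx <- length(field$x); ny <- length(field$y)
  js <- which(field$x >= prior[1] - 1e-9 & field$x <= prior[2] + 1e-9)
  ks <- which(field$y >= prior[3] - 1e-9 & field$y <= prior[4] + 1e-9)
  m <- obs$detections
  dx_i <- floor(obs$perceived[, 1] / field$hx + 0.5)
  dy_i <- floor(obs$perceived[, 2] / field$hy + 0.5)
  best <- -Inf; bj <- NA; bk <- NA
  for (j in js) for (k in ks) {
    lp <- 0
    for (i in seq_along(m)) {
      jj <- min(max(j + dx_i[i], 1), nx)
      kk <- min(max(k + dy_i[i], 1), ny)
      lp <- lp + if (m[i] == 1) logA[jj, kk] else logB[jj, kk]
    }
    if (lp > best) { best <- lp; bj <- j; bk <- k }
  }
  list(xhat = field$x[bj], yhat = field$y[bk], value = best)
}

# aggregate MSEx over non-excluded records
agg_msex <- function(records) {
  keep <- !records$excluded
  mean((records$xhat[keep] - records$x[keep])^2)
}

# paired mean difference of per-realization squared errors in x between two
# record sets sharing (loc_id, rep); returns mean difference and its MC
# standard error over the pairs where both are non-excluded
paired_se_diff <- function(rec_a, rec_b) {
  key_a <- paste(rec_a$loc_id, rec_a$rep)
  key_b <- paste(rec_b$loc_id, rec_b$rep)
  common <- intersect(key_a[!rec_a$excluded], key_b[!rec_b$excluded])
  ia <- match(common, key_a); ib <- match(common, key_b)
  d <- (rec_a$xhat[ia] - rec_a$x[ia])^2 - (rec_b$xhat[ib] - rec_b$x[ib])^2
  list(mean = mean(d), se = stats::sd(d) / sqrt(length(d)), n = length(d))
}
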