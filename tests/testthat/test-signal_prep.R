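test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h$values[1], 0)
  expect_equal(max(h$values), 1)
  # mode of the difference of gammas, located on a dense grid
  expect_equal(h$t[which.max(h$values)], 5.0, tolerance = 0.2)
  # single global maximum
  expect_equal(sum(abs(h$values - 1) < 1e-12), 1)
  expect_error(canonical_hrf(0), "TR")
})

test_that("HRF convolution is a causal LTI operation", {
  h <- canonical_hrf(2)
  n <- 100
  y <- hrf_convolve(rep(1, n), h)
  burn <- length(h$values)
  expect_equal(unname(y[(burn + 1):n]), rep(sum(h$values), n - burn),
               tolerance = 1e-10)
  # impulse at t0 cannot influence earlier samples
  imp <- hrf_convolve(c(rep(0, 10), 1, rep(0, 40)), h)
  expect_true(all(abs(imp[1:10]) < 1e-12))
})

test_that("build_nuisance assembles the expected columns", {
  p <- make_paradigm()
  motion <- matrix(rnorm(p$n_volumes * 6, sd = 0.01), ncol = 6)
  m <- build_nuisance(p, motion, TR = 2, n_volumes = p$n_volumes)
  expect_equal(ncol(m$X), 14)  # task + 6 motion + 6 derivatives + intercept
  expect_equal(m$labels[1], "task")
  expect_equal(nrow(m$X), p$n_volumes)

  # zero motion: the 12 motion columns are flagged and dropped
  m0 <- build_nuisance(p, matrix(0, p$n_volumes, 6), 2, p$n_volumes)
  expect_equal(length(m0$dropped), 12)
  expect_equal(ncol(m0$X), 2)   # task + intercept

  expect_error(build_nuisance(p, matrix(0, 10, 6), 2, p$n_volumes), "rows")
})

test_that("convolved task regressor peaks well after block onset", {
  p <- make_paradigm(n_task_blocks = 1, final_rest_duration = 60)
  m <- build_nuisance(p, NULL, TR = 2, n_volumes = p$n_volumes)
  reg <- m$X[, m$labels == "task"]
  onset <- p$blocks$onset[p$blocks$condition == "task"][1]
  t_peak <- (which.max(reg) - 1) * 2
  expect_gte(t_peak - onset, 4)
})

test_that("regress_out matches the normal-equations oracle", {
  set.seed(31)
  n <- 80
  X <- cbind(1, rnorm(n), rnorm(n))
  ts <- matrix(rnorm(n * 4), n, 4)
  model <- structure(list(X = X, labels = c("i", "a", "b"),
                          dropped = character(0)), class = "dfnc_nuisance")
  res <- regress_out(ts, model)
  hat <- X %*% solve(t(X) %*% X) %*% t(X)
  expect_equal(res, ts - hat %*% ts, tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(t(res) %*% X)) /
              (max(abs(ts)) * max(abs(X)) * n), 1e-8)
  # idempotence
  expect_equal(regress_out(res, model), res, tolerance = 1e-10)
})

test_that("regress_out handles trivial and degenerate models", {
  set.seed(32)
  n <- 50
  ts <- matrix(rnorm(n * 2), n, 2)
  icpt <- structure(list(X = matrix(1, n, 1), labels = "intercept",
                         dropped = character(0)), class = "dfnc_nuisance")
  expect_equal(regress_out(ts, icpt), scale(ts, scale = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a column of the model regresses to ~0
  v <- rnorm(n)
  model <- structure(list(X = cbind(1, v), labels = c("i", "v"),
                          dropped = character(0)), class = "dfnc_nuisance")
  expect_lt(max(abs(regress_out(cbind(v), model))), 1e-10)
  # collinear columns are dropped with a warning
  model2 <- structure(list(X = cbind(1, v, 2 * v), labels = c("i", "v", "v2"),
                           dropped = character(0)), class = "dfnc_nuisance")
  expect_warning(r2 <- regress_out(ts, model2), "collinear")
  expect_equal(r2, regress_out(ts, model), tolerance = 1e-10)
})

test_that("detrend_lowpass removes trends and respects the passband", {
  TR <- 2
  n <- 197
  tt <- seq_len(n)
  ramp <- cbind(5 + 0.3 * tt)
  out <- detrend_lowpass(ramp, TR)
  expect_lt(max(abs(out)), 1e-8 * diff(range(ramp)))

  amp_after <- function(f) {
    x <- sin(2 * pi * f * tt * TR)
    y <- detrend_lowpass(cbind(x), TR)[, 1]
    # amplitude via projection on the quadrature pair, away from the edges
    mid <- 30:(n - 30)
    basis <- cbind(sin(2 * pi * f * tt * TR), cos(2 * pi * f * tt * TR))[mid, ]
    sqrt(sum(qr.coef(qr(basis), y[mid])^2))
  }
  expect_gte(amp_after(0.05), 0.95)           # passband retained
  expect_lt(amp_after(0.2), 10^(-20 / 20))    # >= 20 dB attenuation

  expect_error(detrend_lowpass(cbind(rnorm(100)), TR, cutoff = 0.3),
               "Nyquist")
  expect_error(detrend_lowpass(cbind(rnorm(10)), TR), "30 samples")
})

test_that("detrend_lowpass is linear and length preserving", {
  set.seed(33)
  TR <- 2
  x <- rnorm(120); y <- rnorm(120)
  fx <- detrend_lowpass(cbind(x), TR)
  fy <- detrend_lowpass(cbind(y), TR)
  fxy <- detrend_lowpass(cbind(2 * x - 3 * y), TR)
  expect_equal(nrow(fx), 120)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("framewise displacement follows the Power formulation", {
  expect_equal(framewise_displacement(matrix(0, 20, 6)), rep(0, 20))

  m <- matrix(0, 10, 6)
  m[5:10, 1] <- 1  # single 1 mm x-translation step at frame 5
  fd <- framewise_displacement(m)
  expect_equal(fd, c(rep(0, 4), 1, rep(0, 5)))

  r <- matrix(0, 6, 6)
  r[3:6, 5] <- 0.01  # 0.01 rad rotation step -> 0.5 mm at 50 mm radius
  expect_equal(framewise_displacement(r)[3], 0.5)

  # invariant to constant offsets per column
  set.seed(34)
  mm <- matrix(rnorm(60), 10, 6)
  off <- sweep(mm, 2, runif(6, -5, 5), "+")
  expect_equal(framewise_displacement(mm), framewise_displacement(off),
               tolerance = 1e-12)

  expect_error(framewise_displacement(matrix(0, 5, 4)), "6 columns")
})
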