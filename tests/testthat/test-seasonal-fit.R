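test_that("noiseless cosine round-trips exactly", {
  ts <- make_cosine_seq(A = 3, X = 25, x0 = 10, M = -5, step = 1, span = 30)
  f <- fit_seasonal_cosine(ts, force = TRUE)
  expect_true(f$converged)
  expect_equal(f$A, 3, tolerance = 1e-6)
  expect_equal(f$X, 25, tolerance = 1e-6)
  expect_equal(f$x0, 10, tolerance = 1e-5)
  expect_equal(f$M, -5, tolerance = 1e-6)
  expect_equal(f$x0_over_X, 0.4, tolerance = 1e-6)
  expect_lt(f$rmse, 1e-6)
  # the fitted curve attains its maximum at x = x0
  expect_equal(predict(f, f$x0), f$A + f$M, tolerance = 1e-8)
  expect_true(all(predict(f, seq(0, 30, 0.1)) <= f$A + f$M + 1e-8))
})

test_that("x0 is reported folded into [0, X)", {
  # generate with x0 outside one period
  ts <- make_cosine_seq(A = 3, X = 20, x0 = 33, M = -4, step = 1.2, span = 28)
  f <- fit_seasonal_cosine(ts, force = TRUE)
  expect_gte(f$x0_over_X, 0)
  expect_lt(f$x0_over_X, 1)
  expect_equal(f$x0_over_X, 13 / 20, tolerance = 1e-5)
})

test_that("translation of distances shifts x0 and nothing else", {
  x <- seq(0, 30, 1.5)
  y <- 3.2 * cos(2 * pi * (x - 7) / 24) - 5.5
  f0 <- fit_seasonal_cosine(tooth_sequence("a", x, y), force = TRUE)
  fc <- fit_seasonal_cosine(tooth_sequence("b", x + 4, y), force = TRUE)
  expect_equal(fc$A, f0$A, tolerance = 1e-6)
  expect_equal(fc$X, f0$X, tolerance = 1e-6)
  expect_equal(fc$M, f0$M, tolerance = 1e-6)
  expect_equal(fc$rmse, f0$rmse, tolerance = 1e-8)
  expect_lt(circ_err(fc$x0, f0$x0 + 4, period = f0$X), 1e-5)
})

test_that("noisy fit matches the exhaustive grid-search oracle", {
  g <- gen_tooth_sequence(A = 3, X = 25, x0 = 10, M = -5, sigma = 0.3,
                          step = 1.5, crown_length = 28.5, seed = 2024)
  x <- g$seq$distance_mm; y <- g$seq$d18O
  f <- fit_seasonal_cosine(g$seq, force = TRUE)
  orc <- grid_cosine_oracle(x, y)
  # fit must be at least as good as the brute-force grid optimum
  sse_fit <- sum(residuals(f)^2)
  expect_lte(sse_fit, orc$sse + 1e-8)
  # and agree with the oracle at the oracle's grid resolution
  expect_lt(abs(f$A - orc$A), 0.1)
  expect_lt(abs(f$X - orc$X), 0.25)
  expect_lt(circ_err(f$x0_over_X, orc$x0_over_X), 0.005 + 1e-9)
  expect_lt(abs(f$M - orc$M), 0.1)
})

test_that("x0/X is recovered across simulated teeth", {
  teeth <- gen_tooth_set(n = 40, sigma = 0.3, n_samples = 15, seed = 42)
  res <- vapply(teeth, function(tt) {
    f <- fit_seasonal_cosine(tt$seq, force = TRUE)
    c(err = circ_err(f$x0_over_X, tt$truth$x0_over_X),
      Xerr = f$X - tt$truth$X, conv = as.numeric(f$converged))
  }, numeric(3))
  expect_lte(median(res["err", ]), 0.03)
  expect_gte(mean(res["conv", ]), 0.95)
  # recovered periods scatter around the truth rather than to one side
  expect_lt(abs(median(res["Xerr", ])), 1)
})

test_that("drift model recovers a linear trend on top of the cosine", {
  x <- seq(0, 30, 1.2)
  y <- 3 * cos(2 * pi * (x - 10) / 25) - 5 + 0.05 * x
  f <- fit_seasonal_cosine(tooth_sequence("d", x, y), model = "drift", force = TRUE)
  expect_equal(f$drift_slope, 0.05, tolerance = 1e-4)
  expect_equal(f$A, 3, tolerance = 1e-3)
  expect_lt(circ_err(f$x0, 10, period = f$X), 0.01)
})

test_that("damped model recovers amplitude attenuation towards the ERJ", {
  x <- seq(0, 30, 1.2)
  X_B <- 30; X_A <- 18
  y <- 3 * exp((x - X_B) / X_A) * cos(2 * pi * (x - 10) / 25) - 5
  f <- fit_seasonal_cosine(tooth_sequence("dmp", x, y), model = "damped", force = TRUE)
  expect_equal(f$damping$X_A, 18, tolerance = 0.05)
  expect_equal(f$A, 3, tolerance = 0.05)
  expect_lt(f$rmse, 0.01)
})

test_that("screening gate is enforced unless forced", {
  x <- seq(0, 28.5, 1.5)
  ramp <- tooth_sequence("r", x, seq(-9, -2, length.out = length(x)))
  expect_error(fit_seasonal_cosine(ramp), "fails screening")
  expect_s3_class(fit_seasonal_cosine(ramp, force = TRUE), "seasonal_fit")
})

test_that("accessor methods are consistent", {
  ts <- make_cosine_seq()
  f <- fit_seasonal_cosine(ts, force = TRUE)
  expect_named(coef(f), c("A", "X", "x0", "M", "x0_over_X"))
  expect_equal(fitted(f) + residuals(f), ts$d18O, tolerance = 1e-10)
  expect_output(print(f), "Cosine seasonality fit")
  expect_output(print(summary(f)), "x0/X")
})
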