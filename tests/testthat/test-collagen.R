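test_that("atomic C:N ratio is computed and scale-invariant", {
  expect_equal(round(cn_atomic(45, 16), 2), 3.28)
  expect_equal(round(cn_atomic(43, 15.7), 2), 3.19)
  expect_equal(cn_atomic(20, 20), 14.007 / 12.011, tolerance = 1e-12)
  expect_equal(cn_atomic(45, 16), cn_atomic(4.5, 1.6), tolerance = 1e-12)
  expect_error(cn_atomic(0, 16), "positive")
  expect_error(cn_atomic(45, -1), "positive")
})

test_that("collagen QC applies the C:N window and yield floor", {
  df <- data.frame(d13C = c(-18, -17, -17.5), d15N = c(7, 8, 7.5),
                   pctC = c(43, 43, 43), pctN = c(15.7, 11, 15.7),
                   yield = c(5, 5, 0.5))
  qc <- collagen_qc(df)
  expect_equal(qc$qc_pass, c(TRUE, FALSE, FALSE))
  expect_equal(qc$cn_atomic[1], cn_atomic(43, 15.7))
})

test_that("iso_summary uses the sample standard deviation", {
  s <- iso_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  one <- iso_summary(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(iso_summary(numeric(0)), "no values")
})

test_that("correlation handles exact, degenerate and permuted cases", {
  x <- c(1, 2, 4, 5, 7, 9)
  r <- correlate(x, x)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$spearman_rho, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$pearson_r, -1, tolerance = 1e-12)
  # symmetric in its arguments
  y <- c(2, 1, 5, 3, 9, 4)
  expect_equal(correlate(x, y)$pearson_r, correlate(y, x)$pearson_r)
  # invariant to affine transforms
  expect_equal(correlate(x, y)$pearson_r, correlate(2 * x + 3, y)$pearson_r,
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 6)), "zero variance")
  p <- correlate(x, x, n_perm = 199, seed = 7)
  expect_lt(p$perm_p, 0.05)
})

test_that("IQR screening uses type-7 quartiles and single-pass fences", {
  r <- iqr_outliers(c(1, 2, 3, 4, 100))
  expect_equal(r$flagged, 100)
  expect_equal(r$kept, c(1, 2, 3, 4))
  expect_equal(r$fences, c(-1, 7))  # Q1 = 2, Q3 = 4 under type 7
  expect_length(iqr_outliers(rep(3, 10))$flagged, 0)
  d <- c(-2, -1, 0, 1, 2)
  expect_equal(iqr_outliers(d)$kept, d)
  expect_warning(iqr_outliers(c(1, 2, 3)), "fewer than 4")
})

test_that("confidence ellipse matches the chi-square geometry", {
  # exact identity-covariance sample: circle of radius sqrt(5.991)
  # four points at +/- sqrt(3/2) on each axis have exactly unit covariance
  xy <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(1.5)
  e <- confidence_ellipse(xy)
  expect_equal(unname(e$center), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-9)

  # diagonal covariance diag(4, 1): axes scale with sqrt of eigenvalues
  set.seed(9)
  z <- MASS::mvrnorm(500, c(0, 0), diag(c(4, 1)), empirical = TRUE)
  e2 <- confidence_ellipse(z)
  expect_equal(unname(e2$semi_axes),
               c(2, 1) * sqrt(qchisq(0.95, 2)), tolerance = 1e-6)

  # rotation equivariance
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e3 <- confidence_ellipse(z %*% t(R))
  expect_equal(unname(e3$semi_axes), unname(e2$semi_axes), tolerance = 1e-6)
  ang <- (e3$rotation - e2$rotation) %% pi
  expect_true(abs(ang - th) < 1e-6 || abs(ang - th - pi) < 1e-6)

  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  # hand-computed: groups {1,2,3} and {2,3,4}
  # SSB = 3*(2-2.5)^2 + 3*(3-2.5)^2 = 1.5; SSW = 2 + 2 = 4
  # F = (1.5/1) / (4/4) = 1.5
  a <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$F, 1.5, tolerance = 1e-12)
  expect_equal(a$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  same <- oneway_anova(list(c(5, 5, 5), c(5, 5)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  sep <- oneway_anova(list(rep(0, 3), rep(10, 3)))
  expect_lt(sep$p, 1e-6)

  expect_error(oneway_anova(list(1:3)), ">= 2 groups")
})
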