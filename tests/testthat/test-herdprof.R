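test_that("Dirichlet posterior means are analytic and MC-consistent", {
  p <- dirichlet_profile(mortality_counts(c(2, 3, 5)), prior = 1,
                         n_draws = 5000, seed = 11)
  expect_equal(p$classes$prop, c(3, 4, 6) / 13, tolerance = 1e-12)
  # Monte-Carlo draw means agree with the analytic posterior mean
  mc_mean <- (p$classes$lower + p$classes$upper) / 2  # rough centre
  expect_true(all(abs(mc_mean - p$classes$prop) < 0.05))
  expect_equal(sum(p$classes$prop), 1, tolerance = 1e-12)
})

test_that("Monte-Carlo intervals match analytic Beta marginals", {
  p <- dirichlet_profile(mortality_counts(c(12, 30, 58)), prior = 1,
                         n_draws = 10000, seed = 21)
  expect_true(all(abs(p$classes$lower - p$classes$beta_lower) < 0.01))
  expect_true(all(abs(p$classes$upper - p$classes$beta_upper) < 0.01))
  expect_true(all(p$classes$lower <= p$classes$prop))
  expect_true(all(p$classes$upper >= p$classes$prop))
})

test_that("concentrated counts give a near-degenerate interval", {
  p <- dirichlet_profile(mortality_counts(c(1000, 0, 0)), prior = 1,
                         n_draws = 5000, seed = 31)
  expect_gte(p$classes$lower[1], 0.99)
  expect_lte(p$classes$upper[1], 1)
})

test_that("survivorship decreases monotonically with interval order intact", {
  p <- dirichlet_profile(mortality_counts(c(0, 0, 3, 5, 4, 6, 9, 7, 2)),
                         n_draws = 4000, seed = 41)
  expect_true(all(diff(p$classes$surv) <= 1e-12))
  expect_true(all(diff(p$classes$surv_lower) <= 1e-9))
  expect_true(all(diff(p$classes$surv_upper) <= 1e-9))
  expect_true(all(p$classes$surv_lower <= p$classes$surv + 1e-12))
  expect_true(all(p$classes$surv_upper >= p$classes$surv - 1e-12))
})

test_that("fractional counts and priors are validated", {
  expect_s3_class(mortality_counts(c(1.5, 0.5, 2)), "mortality_counts")
  expect_error(mortality_counts(c(-1, 2)), ">= 0")
  expect_error(dirichlet_profile(mortality_counts(c(0, 0)), prior = 0, seed = 1),
               "all-zero")
  expect_error(dirichlet_profile(mortality_counts(c(1, 2)), ), "seed")
  expect_equal(payne_classes()$class, LETTERS[1:9])
})

test_that("taphonomy proportions carry Wilson intervals", {
  tp <- taphonomy_proportions(c(burning = 21, gnawing = 1, butchery = 70,
                                none = 0, all = 410), nisp = 410)
  expect_equal(tp$proportion_pct[tp$flag == "butchery"], 100 * 70 / 410,
               tolerance = 1e-9)
  expect_equal(tp$proportion_pct[tp$flag == "none"], 0)
  expect_equal(tp$proportion_pct[tp$flag == "all"], 100)
  # Wilson intervals bracket the estimate away from the boundaries
  b <- tp[tp$flag == "burning", ]
  expect_lt(b$lower_pct, b$proportion_pct)
  expect_gt(b$upper_pct, b$proportion_pct)
  expect_error(taphonomy_proportions(c(x = 5), nisp = 0), "nisp")
  expect_error(taphonomy_proportions(c(x = 500), nisp = 410), "\\[0, nisp\\]")
})

test_that("completeness index is a mean of fractions in percent", {
  expect_equal(completeness_index(c(1, 1, 1)), 100)
  expect_equal(completeness_index(c(1, 0.5)), 75)
  expect_error(completeness_index(numeric(0)), "no completeness")
  expect_error(completeness_index(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("MAU% normalises by expected counts and the maximum element", {
  m <- mau_percent(c(humerus = 10, femur = 5), expected = 2)
  expect_equal(m$mau_pct, c(100, 50))
  expect_equal(mau_percent(c(astragalus = 7), expected = 2)$mau_pct, 100)
  # scale invariance
  m2 <- mau_percent(c(humerus = 20, femur = 10), expected = 2)
  expect_equal(m2$mau_pct, m$mau_pct)
  expect_error(mau_percent(c(a = 0, b = 0), 2), "all element counts")
})

test_that("density-mediated attrition test reports both correlations", {
  dens <- data.frame(element = letters[1:6], density = seq(0.3, 0.8, 0.1))
  # MAU% strictly increasing in density: perfect rank correlation
  mau <- data.frame(element = letters[1:6], mau_pct = c(10, 25, 40, 60, 80, 100))
  r <- density_attrition_test(mau, dens)
  expect_equal(r$spearman_rho, 1, tolerance = 1e-12)
  expect_equal(r$verdict, "attrition signal")

  # constant MAU%: nothing to explain
  flatm <- data.frame(element = letters[1:6], mau_pct = rep(100, 6))
  r2 <- density_attrition_test(flatm, dens)
  expect_equal(r2$verdict, "no attrition signal")
  expect_true(is.na(r2$spearman_rho))

  expect_error(density_attrition_test(
    data.frame(element = c(letters[1:5], "zz"), mau_pct = 1:6), dens), "zz")
})
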