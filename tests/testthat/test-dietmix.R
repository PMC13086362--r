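test_that("plant-to-tissue end-member arithmetic is exact", {
  # enamel: plant mean + Suess (+1.5) + enrichment (+14.1)
  expect_equal(endmember_from_plants(-27.18, "enamel")$mean, -11.58,
               tolerance = 1e-9)
  # collagen: plant mean + Suess (+1.5) + diet-to-collagen (+5.0)
  expect_equal(endmember_from_plants(-26.8, "collagen")$mean, -20.3,
               tolerance = 1e-9)
  # identity when corrections are switched off
  cfg0 <- mixing_config(suess_correction = 0, enamel_enrichment_epsilon = 1e-9)
  expect_equal(endmember_from_plants(c(-25, -27), "enamel", cfg0)$mean, -26,
               tolerance = 1e-6)
  expect_equal(endmember_from_plants(c(-25, -27), "enamel", cfg0)$sd, sqrt(2),
               tolerance = 1e-9)
  expect_error(endmember_from_plants(numeric(0), "enamel"), "no plant values")
})

test_that("linear and exact enrichment forms agree to < 0.5 permil", {
  cfg_lin <- mixing_config(enrichment_form = "linear_addition")
  cfg_alp <- mixing_config(enrichment_form = "alpha_exact")
  for (v in seq(-30, -10, by = 1)) {
    d <- abs(endmember_from_plants(v, "enamel", cfg_lin)$mean -
               endmember_from_plants(v, "enamel", cfg_alp)$mean)
    expect_lt(d, 0.5)
  }
})

test_that("pct_c4 maps end-points, midpoint and printed extremes correctly", {
  expect_equal(pct_c4(-11.58, "enamel")$pct_C4, 0)
  expect_equal(pct_c4(4.18, "enamel")$pct_C4, 100)
  expect_equal(pct_c4(-3.70, "enamel")$pct_C4, 50, tolerance = 1e-9)
  expect_equal(pct_c4(-19.1, "collagen")$pct_C4, 100 * 1.2 / 14,
               tolerance = 1e-9)
  expect_equal(pct_c4(-16.3, "collagen")$pct_C4, 100 * 4 / 14,
               tolerance = 1e-9)
})

test_that("values past the end-members clip with a flag", {
  r <- pct_c4(c(-13, -11.58, 5), "enamel")
  expect_equal(r$pct_C4, c(0, 0, 100))
  expect_equal(r$clipped, c(TRUE, FALSE, TRUE))
  expect_equal(r$pct_C3 + r$pct_C4, rep(100, 3))
})

test_that("water-stressed C3 ceiling is flagged for enamel only", {
  r <- pct_c4(c(-8, -6), "enamel")
  expect_equal(r$exceeds_water_stressed_c3_limit, c(FALSE, TRUE))
  expect_false("exceeds_water_stressed_c3_limit" %in%
                 names(pct_c4(-18, "collagen")))
})

test_that("mixing is affine and inverts to machine precision", {
  # affine: three collinear d13C values give collinear percentages
  p <- pct_c4(c(-10, -6, -2), "enamel")$pct_C4
  expect_equal(p[2] - p[1], p[3] - p[2], tolerance = 1e-9)
  # inversion property over the unclipped range
  for (tissue in c("enamel", "collagen")) {
    for (pc in seq(0, 100, by = 5)) {
      back <- pct_c4(d13c_from_pct_c4(pc, tissue), tissue)$pct_C4
      expect_equal(back, pc, tolerance = 1e-9)
    }
  }
})

test_that("degenerate end-members error", {
  expect_error(mixing_config(enamel_c4_endmember = -11.58), "exceed")
})

test_that("seasonal diet labels follow the fitted d18O phase", {
  # constant pure-C3 diet: all seasonal means 0
  g0 <- gen_tooth_sequence(A = 3, X = 25, x0 = 10, M = -5, sigma = 0,
                           step = 1.2, crown_length = 30,
                           c4_winter = 0, c13_amp = 0, sigma_c = 0, seed = 1)
  f0 <- fit_seasonal_cosine(g0$seq, force = TRUE)
  d0 <- classify_seasonal_diet(f0, g0$seq)
  expect_true(all(abs(d0$per_season$mean_pct_C4) < 1e-6))

  # winter-only C4 pulse peaking at 30%
  g <- gen_tooth_sequence(A = 3, X = 25, x0 = 10, M = -5, sigma = 0,
                          step = 1.2, crown_length = 30,
                          c4_winter = 30, sigma_c = 0, seed = 2)
  f <- fit_seasonal_cosine(g$seq, force = TRUE)
  d <- classify_seasonal_diet(f, g$seq)
  ps <- d$per_sample
  # oracle: mean of the truth C4 curve over the truth-phase winter window
  phase <- (2 * pi * (g$seq$distance_mm - 10) / 25) %% (2 * pi)
  truth_c4 <- 30 * (1 - cos(phase)) / 2
  win <- abs(phase - pi) <= pi / 4
  sum_w <- pmin(phase, 2 * pi - phase) <= pi / 4
  expect_equal(ps$pct_C4[ps$season == "winter"], truth_c4[win],
               tolerance = 1e-6)
  expect_equal(d$per_season$mean_pct_C4[d$per_season$season == "winter"],
               mean(truth_c4[win]), tolerance = 1e-6)
  expect_lt(d$per_season$mean_pct_C4[d$per_season$season == "summer"],
            mean(truth_c4[win]) / 10)

  # no converged fit: error
  f$converged <- FALSE
  expect_error(classify_seasonal_diet(f, g$seq), "converged")
})

test_that("the shipped mixing configuration file round-trips", {
  cfg <- read_mixing_config(system.file("extdata", "mixing_config.yaml",
                                        package = "herdseason"))
  expect_equal(cfg$enamel_c3_endmember, -11.58)
  expect_equal(cfg$collagen_c4_endmember, -6.3)
  expect_equal(cfg$enrichment_form, "linear_addition")
  expect_equal(pct_c4(-3.70, "enamel", cfg)$pct_C4, 50, tolerance = 1e-9)
})
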