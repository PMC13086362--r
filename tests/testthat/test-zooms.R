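test_that("flat spectra yield empty peak lists", {
  mz <- seq(900, 4000, 0.5)
  pk <- process_spectrum(maldi_spectrum(mz, rep(5, length(mz))))
  expect_equal(nrow(pk), 0)
})

test_that("a clean Gaussian peak is centroided accurately", {
  mz <- seq(900, 4000, 0.2)
  int <- 100 * exp(-(mz - 3033.4)^2 / (2 * 0.8^2))
  pk <- process_spectrum(maldi_spectrum(mz, int))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 3033.4), 0.05)
})

test_that("peaks below the signal-to-noise threshold are rejected", {
  # marker amplitude only 2.5x the noise sd: below the 3.5 threshold
  g <- gen_maldi_spectrum("Ovis", snr = 2.5, seed = 12)
  pk <- process_spectrum(g$spectrum)
  hits <- pk$mz[abs(pk$mz - 3033.4) <= 0.5]
  expect_length(hits, 0)
})

test_that("taxon calls follow the decisive-marker logic", {
  expect_equal(call_taxon(fake_peaklist(3033.4))$call, "Ovis")
  expect_equal(call_taxon(fake_peaklist(3017.4))$call, "Ovis")
  expect_equal(call_taxon(fake_peaklist(3093.4))$call, "Capra")
  expect_equal(call_taxon(fake_peaklist(c(3033.4, 3093.4)))$call, "Ambiguous")
  expect_equal(call_taxon(fake_peaklist(c(1500, 2500)))$call, "Indeterminate")
  # caprine-informative 375 masses never decide a call
  expect_equal(call_taxon(fake_peaklist(c(1154, 2028, 2044)))$call,
               "Indeterminate")
  expect_error(call_taxon(fake_peaklist(3033.4), tolerance = 0), "> 0")
})

test_that("calls are invariant to intensity rescaling", {
  g <- gen_maldi_spectrum("Capra", snr = 15, seed = 33)
  sp <- g$spectrum
  scaled <- maldi_spectrum(sp$mz, sp$intensity * 40, sp$specimen_id)
  p1 <- process_spectrum(sp); p2 <- process_spectrum(scaled)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$snr, p2$snr, tolerance = 1e-8)
  expect_equal(call_taxon(p1)$call, call_taxon(p2)$call)
})

test_that("increasing the tolerance never unmatches a marker", {
  for (seed in 1:5) {
    g <- gen_maldi_spectrum(if (seed %% 2) "Ovis" else "Capra",
                            snr = 12, seed = seed)
    pk <- process_spectrum(g$spectrum)
    m1 <- call_taxon(pk, tolerance = 0.25)$evidence$matched
    m2 <- call_taxon(pk, tolerance = 0.5)$evidence$matched
    expect_true(all(m2[m1]))
  }
})

test_that("batch reports tabulate calls deterministically", {
  specs <- c(lapply(1:6, function(i)
               gen_maldi_spectrum("Ovis", snr = 15, seed = 100 + i,
                                  specimen_id = sprintf("ov%02d", i))$spectrum),
             lapply(1:2, function(i)
               gen_maldi_spectrum("Capra", snr = 15, seed = 200 + i,
                                  specimen_id = sprintf("cap%02d", i))$spectrum))
  rep <- batch_report(specs)
  expect_equal(unname(rep$summary[c("Ovis", "Capra")]), c(6L, 2L),
               ignore_attr = TRUE)
  expect_equal(nrow(rep$calls), 8)
  expect_error(batch_report(list()), "no spectra")
})

test_that("a spectrum carrying both genera's markers is Ambiguous", {
  mz <- seq(900, 4000, 0.25)
  int <- 100 * exp(-(mz - 3033.4)^2 / (2 * 0.8^2)) +
         100 * exp(-(mz - 3093.4)^2 / (2 * 0.8^2))
  tc <- call_taxon(process_spectrum(maldi_spectrum(mz, int, "mix")))
  expect_equal(tc$call, "Ambiguous")
  expect_equal(tc$specimen_id, "mix")
})

test_that("two-column text spectra round-trip through the reader", {
  g <- gen_maldi_spectrum("Ovis", snr = 20, mz_step = 1, seed = 9,
                          specimen_id = "file1")
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(mz = g$spectrum$mz, intensity = g$spectrum$intensity),
              path, row.names = FALSE)
  sp <- read_spectrum(path)
  expect_equal(sp$mz, g$spectrum$mz)
  expect_equal(sp$intensity, g$spectrum$intensity, tolerance = 1e-9)
  expect_error(read_spectrum(tempfile()), "not found")
})

test_that("malformed spectra are rejected by the container", {
  expect_error(maldi_spectrum(c(1000, 999), c(1, 1)), "increasing")
  expect_error(maldi_spectrum(c(999, 1000), c(-1, 1)), ">= 0")
  expect_error(process_spectrum(maldi_spectrum(1:50, rep(1, 50))), "100 points")
})
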