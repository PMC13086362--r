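# Seeded synthetic-data generators.
#
# Every generator returns the simulated dataset together with the ground
# truth used to produce it, so any downstream estimate can be scored. One
# parent seed fans out to per-object child seeds through a counter scheme
# (see child_seed), which keeps earlier objects stable when more are
# generated.

#' Simulate one intra-tooth isotope sequence
#'
#' d18O follows the cosine seasonality model plus Gaussian analytical noise;
#' d13C is produced by pushing a seasonal C4-fraction curve through the
#' inverse mixing model with its own noise. The C4 curve is a raised cosine
#' peaking half a cycle after the d18O maximum (a winter C4 pulse) scaled to
#' `c4_winter` percent, so the generated carbon series sits in strict
#' opposition to oxygen when `c4_winter > 0`; when `c4_winter = 0` the
#' carbon series is an explicit sinusoid offset from oxygen by
#' `c13_phase_offset_deg`.
#'
#' Defaults mimic the archaeological study conditions: amplitudes of a few
#' permil, periods of 18-30 mm of crown per annual cycle, a 1.2 mm sampling
#' step and 10-20 increments per tooth.
#'
#' @param A,X,x0,M Cosine truth: amplitude (permil), period (mm), position
#'   of the d18O maximum (mm), mean (permil).
#' @param sigma Gaussian noise sd for d18O (permil). Default 0.3.
#' @param step Sampling step (mm). Default 1.2.
#' @param crown_length Sampled crown span (mm). Default 18.
#' @param c4_winter Peak winter C4 percentage of diet. Default 0 (pure C3).
#' @param c13_amp Amplitude of the d13C sinusoid when `c4_winter = 0`
#'   (permil). Default 1.
#' @param c13_phase_offset_deg Phase offset of d13C relative to d18O
#'   (degrees). Default 180 (opposition).
#' @param sigma_c Gaussian noise sd for d13C (permil). Default 0.15.
#' @param cfg [mixing_config()] used for the inverse mixing step.
#' @param specimen_id,taxon Passed to [tooth_sequence()].
#' @param seed Seed; required.
#' @return List `seq` (a [tooth_sequence()]) and `truth` (named list of all
#'   generating parameters, including the seed).
#' @export
gen_tooth_sequence <- function(A = 3, X = 25, x0 = 10, M = -5, sigma = 0.3,
                               step = 1.2, crown_length = 18,
                               c4_winter = 0, c13_amp = 1,
                               c13_phase_offset_deg = 180, sigma_c = 0.15,
                               cfg = mixing_config(),
                               specimen_id = "sim", taxon = "OvisCapra",
                               seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (step <= 0 || crown_length < 4 * step) {
    stop("invalid geometry: need step > 0 and crown_length >= 4*step", call. = FALSE)
  }
  x <- seq(0, crown_length, by = step)
  mu_o <- A * cos(2 * pi * (x - x0) / X) + M
  if (c4_winter > 0) {
    frac <- c4_winter * (1 - cos(2 * pi * (x - x0) / X)) / 2  # peaks at winter
    mu_c <- d13c_from_pct_c4(frac, "enamel", cfg)
  } else {
    off <- c13_phase_offset_deg * pi / 180
    # d18O max at x0 corresponds to sine phase pi/2; add the offset for C
    mu_c <- c13_amp * sin(2 * pi * (x - x0) / X + pi / 2 + off) +
      d13c_from_pct_c4(0, "enamel", cfg)
  }
  vals <- with_seed(seed, {
    list(o = mu_o + stats::rnorm(length(x), 0, sigma),
         c = mu_c + stats::rnorm(length(x), 0, sigma_c))
  })
  truth <- list(A = A, X = X, x0 = x0, M = M, x0_over_X = (x0 %mod% X) / X,
                sigma = sigma, step = step, crown_length = crown_length,
                c4_winter = c4_winter, c13_amp = c13_amp,
                c13_phase_offset_deg = c13_phase_offset_deg,
                sigma_c = sigma_c, mu_d18O = mu_o, mu_d13C = mu_c,
                seed = seed)
  list(seq = tooth_sequence(specimen_id, x, vals$o, vals$c, taxon = taxon),
       truth = truth)
}

#' Simulate a herd of tooth sequences
#'
#' Draws per-tooth cosine parameters from the stated ranges (defaults:
#' amplitude 2-5 permil, period 18-30 mm, x0/X uniform on \[0, 1),
#' mean -7 to -3 permil) and generates each tooth with a child seed.
#'
#' @param n Number of teeth.
#' @param A_range,X_range,M_range Uniform ranges for the truths.
#' @param sigma Noise sd (permil). Default 0.3.
#' @param n_samples Approximate increments per tooth. Default 15.
#' @param seed Parent seed; required.
#' @return List of `list(seq, truth)` entries (see [gen_tooth_sequence()]).
#' @export
gen_tooth_set <- function(n = 100, A_range = c(2, 5), X_range = c(18, 30),
                          M_range = c(-7, -3), sigma = 0.3, n_samples = 15,
                          seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  pars <- with_seed(seed, {
    data.frame(A = stats::runif(n, A_range[1], A_range[2]),
               X = stats::runif(n, X_range[1], X_range[2]),
               r = stats::runif(n),  # x0/X
               M = stats::runif(n, M_range[1], M_range[2]))
  })
  lapply(seq_len(n), function(i) {
    X <- pars$X[i]
    crown <- (n_samples - 1) * 1.2
    gen_tooth_sequence(A = pars$A[i], X = X, x0 = pars$r[i] * X, M = pars$M[i],
                       sigma = sigma, step = 1.2, crown_length = crown,
                       specimen_id = sprintf("sim%03d", i),
                       seed = child_seed(seed, i))
  })
}

#' Simulate a collagen dataset
#'
#' Bivariate-normal (d13C, d15N); %C uniform in its observed window and %N
#' derived so the atomic C:N ratio lands in the target window; yields
#' uniform. Defaults mimic well-preserved archaeological caprine collagen
#' (d13C -17.7 +/- 0.8 permil, d15N 7.5 +/- 0.9 permil, C:N 3.15-3.35).
#'
#' @param n Number of specimens. Default 18.
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N Marginal moments.
#' @param correlation Correlation of d13C and d15N in \[-1, 1\]. Default 0.1.
#' @param pctC_range %C window. Default c(42, 45).
#' @param cn_range Target atomic C:N window. Default c(3.15, 3.35).
#' @param yield_range Collagen yield window (wt%). Default c(1.1, 11).
#' @param seed Seed; required.
#' @return List `samples` (data frame ready for [collagen_qc()]) and
#'   `truth`.
#' @export
gen_collagen_dataset <- function(n = 18, mean_d13C = -17.7, sd_d13C = 0.8,
                                 mean_d15N = 7.5, sd_d15N = 0.9,
                                 correlation = 0.1,
                                 pctC_range = c(42, 45),
                                 cn_range = c(3.15, 3.35),
                                 yield_range = c(1.1, 11), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (abs(correlation) > 1) stop("|correlation| must be <= 1", call. = FALSE)
  if (sd_d13C < 0 || sd_d15N < 0) stop("sds must be >= 0", call. = FALSE)
  Sigma <- matrix(c(sd_d13C^2, correlation * sd_d13C * sd_d15N,
                    correlation * sd_d13C * sd_d15N, sd_d15N^2), 2)
  out <- with_seed(seed, {
    iso <- MASS::mvrnorm(n, mu = c(mean_d13C, mean_d15N), Sigma = Sigma)
    iso <- matrix(iso, ncol = 2)
    pctC <- stats::runif(n, pctC_range[1], pctC_range[2])
    cn <- stats::runif(n, cn_range[1], cn_range[2])
    data.frame(specimen_id = sprintf("col%03d", seq_len(n)),
               taxon = "OvisCapra",
               d13C = iso[, 1], d15N = iso[, 2],
               pctC = pctC,
               pctN = pctC * 14.007 / (12.011 * cn),
               yield = stats::runif(n, yield_range[1], yield_range[2]),
               stringsAsFactors = FALSE)
  })
  list(samples = out,
       truth = list(n = n, mean_d13C = mean_d13C, sd_d13C = sd_d13C,
                    mean_d15N = mean_d15N, sd_d15N = sd_d15N,
                    correlation = correlation, cn_range = cn_range,
                    seed = seed))
}

#' Simulate mortality counts
#'
#' One multinomial draw over the age classes.
#'
#' @param probs Class probabilities (must sum to 1).
#' @param N Number of individuals.
#' @param labels Optional class labels.
#' @param seed Seed; required.
#' @return List `counts` (a [mortality_counts()]) and `truth`.
#' @export
gen_mortality_counts <- function(probs, N, labels = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("probs must be a probability simplex", call. = FALSE)
  }
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  cnt <- with_seed(seed, drop(stats::rmultinom(1L, N, probs)))
  list(counts = mortality_counts(cnt, labels),
       truth = list(probs = probs, N = N, seed = seed))
}

#' Simulate a MALDI-ToF collagen fingerprint
#'
#' Gaussian peaks at the taxon's decisive marker masses plus shared
#' non-diagnostic collagen peaks, a smooth decaying baseline, and detector
#' noise. Peak amplitude is `snr` times the noise sd. The noise is
#' correlated over about `noise_corr_mz` Da (white noise convolved with a
#' Gaussian kernel, rescaled to `noise_sd`), emulating the smooth residual
#' noise of profile spectra accumulated over thousands of laser shots;
#' uncorrelated per-point noise is not a regime linear-mode MALDI profiles
#' exhibit.
#'
#' @param taxon `"Ovis"` or `"Capra"`.
#' @param snr Target peak signal-to-noise (> 0). Default 20.
#' @param mz_step Sampling step in Da. Default 0.2.
#' @param mz_range Acquisition range. Default c(900, 4000).
#' @param noise_sd Noise sd after correlation. Default 1.
#' @param noise_corr_mz Noise correlation length (Da). Default 0.6.
#' @param peak_sigma Gaussian peak sd in Da. Default 0.8.
#' @param panel Marker panel supplying the decisive masses.
#' @param specimen_id Specimen identifier.
#' @param seed Seed; required.
#' @return List `spectrum` (a [maldi_spectrum()]) and `truth`.
#' @export
gen_maldi_spectrum <- function(taxon = c("Ovis", "Capra"), snr = 20,
                               mz_step = 0.2, mz_range = c(900, 4000),
                               noise_sd = 1, noise_corr_mz = 0.6,
                               peak_sigma = 0.8,
                               panel = caprine_marker_panel(),
                               specimen_id = "simspec", seed) {
  taxon <- match.arg(taxon)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  marker_mz <- panel$mz[panel$decisive & panel$taxon == taxon]
  shared_mz <- c(panel$mz[!panel$decisive], 1105.6, 1427.7, 1580.8, 2131.1, 2883.2)
  shared_mz <- shared_mz[shared_mz >= mz_range[1] & shared_mz <= mz_range[2]]
  amp <- snr * if (noise_sd > 0) noise_sd else 1
  sig <- rep(0, length(mz))
  for (m in marker_mz) sig <- sig + amp * exp(-(mz - m)^2 / (2 * peak_sigma^2))
  for (m in shared_mz) sig <- sig + 0.6 * amp * exp(-(mz - m)^2 / (2 * peak_sigma^2))
  baseline <- 30 * noise_sd * exp(-(mz - mz_range[1]) / 900) +
    2 * noise_sd * sin(2 * pi * (mz - mz_range[1]) / 2500)
  intensity <- if (noise_sd > 0) {
    with_seed(seed, {
      z <- stats::rnorm(length(mz))
      if (noise_corr_mz > 0) {
        half <- max(1L, ceiling(3 * noise_corr_mz / mz_step))
        k <- stats::dnorm(seq(-half, half) * mz_step, sd = noise_corr_mz)
        z <- as.numeric(stats::filter(z, k / sum(k), circular = TRUE))
      }
      pmax(sig + baseline + z / stats::sd(z) * noise_sd, 0)
    })
  } else pmax(sig + baseline, 0)
  list(spectrum = maldi_spectrum(mz, intensity, specimen_id,
                                 metadata = sprintf("synthetic %s, S/N %g", taxon, snr)),
       truth = list(taxon = taxon, snr = snr, marker_mz = marker_mz,
                    shared_mz = shared_mz, noise_sd = noise_sd,
                    noise_corr_mz = noise_corr_mz,
                    peak_sigma = peak_sigma, seed = seed))
}
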