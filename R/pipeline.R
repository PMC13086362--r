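#' Pipeline run configuration
#'
#' Bundles every stage's inputs and options into one serialisable object. A
#' copy of the configuration is written into the output directory of each
#' run for auditability.
#'
#' @param sequences Path to a long-format CSV of intra-tooth sequences (see
#'   [read_tooth_sequences()]), or a list of [tooth_sequence()] objects.
#' @param collagen Path to a collagen CSV (columns `specimen_id`, `d13C`,
#'   `d15N`, `pctC`, `pctN`, `yield`) or a data frame.
#' @param mortality Named/plain numeric vector of per-class death counts, or
#'   a CSV path with columns `class`, `count`.
#' @param spectra Directory or file paths of MALDI spectra, or a list of
#'   [maldi_spectrum()] objects; optional.
#' @param out_dir Output directory.
#' @param mixing [mixing_config()].
#' @param bands [season_bands()].
#' @param rules [screening_rules()].
#' @param prior,n_draws Dirichlet prior pseudo-counts and Monte-Carlo draws.
#' @param tolerance ZooMS mass tolerance (Da).
#' @param maldi [maldi_params()].
#' @param seed Seed used by every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(sequences = NULL, collagen = NULL, mortality = NULL,
                       spectra = NULL, out_dir = tempfile("herdseason_run_"),
                       mixing = mixing_config(), bands = default_season_bands(),
                       rules = screening_rules(), prior = 1, n_draws = 10000L,
                       tolerance = 0.5, maldi = maldi_params(), seed = 1L) {
  structure(list(sequences = sequences, collagen = collagen,
                 mortality = mortality, spectra = spectra, out_dir = out_dir,
                 mixing = mixing, bands = bands, rules = rules, prior = prior,
                 n_draws = n_draws, tolerance = tolerance, maldi = maldi,
                 seed = seed),
            class = "run_config")
}

resolve_sequences <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_tooth_sequences(x) else x
}

resolve_collagen <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("input file not found: %s", x), call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else x
}

resolve_mortality <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "mortality_counts")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("input file not found: %s", x), call. = FALSE)
    df <- utils::read.csv(x, stringsAsFactors = FALSE)
    mortality_counts(df$count, df$class)
  } else mortality_counts(x, names(x))
}

#' Run the full herd-seasonality pipeline
#'
#' Executes, in order: ZooMS identification (taxa feed the sequence labels
#' where specimen ids match), sequence screening + cosine fitting + birth
#' season estimation, per-increment diet mixing with seasonal labels,
#' collagen QC and statistics, and the mortality profile. Per-stage CSVs, a
#' JSON summary and a log (package version, config hash, seed) are written
#' to `config$out_dir`. Stages whose inputs are absent are skipped; a stage
#' failure keeps earlier outputs on disk and re-raises with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-stage results and the summary path.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(package_version = as.character(utils::packageVersion("herdseason")),
                  seed = config$seed)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- ZooMS ---------------------------------------------------------------
  taxa <- NULL
  if (!is.null(config$spectra)) {
    zr <- stage("zooms", batch_report(config$spectra, params = config$maldi,
                                      tolerance = config$tolerance))
    utils::write.csv(zr$calls, file.path(config$out_dir, "zooms_calls.csv"),
                     row.names = FALSE)
    taxa <- stats::setNames(zr$calls$call, zr$calls$specimen_id)
    summary$zooms <- as.list(zr$summary)
    results$zooms <- zr
  }

  # --- sequence modelling --------------------------------------------------
  seqs <- stage("seqmodel", resolve_sequences(config$sequences))
  if (!is.null(seqs)) {
    rows <- list(); diet_rows <- list()
    for (s in seqs) {
      id <- attr(s, "specimen_id")
      if (!is.null(taxa) && id %in% names(taxa) &&
          taxa[[id]] %in% c("Ovis", "Capra")) {
        attr(s, "taxon") <- taxa[[id]]
      }
      scr <- screen_sequence(s, config$rules)
      row <- data.frame(specimen_id = id, taxon = attr(s, "taxon"),
                        eligible = scr$eligible,
                        reasons = paste(scr$reasons, collapse = ";"),
                        A = NA, X = NA, x0 = NA, M = NA, x0_over_X = NA,
                        rmse = NA, converged = NA,
                        angle_deg = NA, season_call = NA, tentative = NA,
                        stringsAsFactors = FALSE)
      if (scr$eligible) {
        fit <- stage("seqmodel", fit_seasonal_cosine(s, rules = config$rules))
        tent <- "no_clear_min" %in% scr$reasons
        bs <- estimate_birth_season(fit, config$bands, tentative = tent)
        row[c("A", "X", "x0", "M", "x0_over_X", "rmse", "converged")] <-
          list(fit$A, fit$X, fit$x0, fit$M, fit$x0_over_X, fit$rmse, fit$converged)
        row[c("angle_deg", "season_call", "tentative")] <-
          list(bs$angle_deg, bs$season_call, bs$tentative)
        if (any(is.finite(s$d13C))) {
          d <- stage("dietmix", classify_seasonal_diet(fit, s, config$mixing))
          ds <- d$per_season
          ds$specimen_id <- id
          diet_rows[[id]] <- ds
        }
      }
      rows[[id]] <- row
    }
    fits <- do.call(rbind, rows)
    utils::write.csv(fits, file.path(config$out_dir, "seasonality_fits.csv"),
                     row.names = FALSE)
    results$fits <- fits
    summary$seasonality <- list(
      n_sequences = nrow(fits), n_modelled = sum(fits$eligible),
      season_calls = as.list(table(fits$season_call[!is.na(fits$season_call)])))
    if (length(diet_rows)) {
      diet <- do.call(rbind, diet_rows)
      rownames(diet) <- NULL
      utils::write.csv(diet, file.path(config$out_dir, "seasonal_diet.csv"),
                       row.names = FALSE)
      results$diet <- diet
      wint <- diet[diet$season == "winter", "mean_pct_C4"]
      summary$diet <- list(winter_mean_pct_C4 = if (length(wint)) mean(wint) else NA)
    }
  }

  # --- collagen ------------------------------------------------------------
  col <- stage("collagen_stats", resolve_collagen(config$collagen))
  if (!is.null(col)) {
    qc <- stage("collagen_stats", collagen_qc(col))
    utils::write.csv(qc, file.path(config$out_dir, "collagen_qc.csv"),
                     row.names = FALSE)
    pass <- qc[qc$qc_pass, ]
    sC <- iso_summary(pass$d13C); sN <- iso_summary(pass$d15N)
    corr <- if (nrow(pass) >= 3) correlate(pass$d13C, pass$d15N) else NULL
    p4 <- pct_c4(pass$d13C, "collagen", config$mixing)
    summary$collagen <- list(
      n = nrow(qc), n_pass = nrow(pass),
      d13C_mean = sC$mean, d13C_sd = sC$sd,
      d15N_mean = sN$mean, d15N_sd = sN$sd,
      cn_range = range(qc$cn_atomic),
      pearson_r = if (!is.null(corr)) corr$pearson_r else NA,
      pct_C4_range = range(p4$pct_C4))
    results$collagen <- qc
  }

  # --- mortality -----------------------------------------------------------
  mc <- stage("herdprof", resolve_mortality(config$mortality))
  if (!is.null(mc)) {
    prof <- stage("herdprof", dirichlet_profile(mc, prior = config$prior,
                                                n_draws = config$n_draws,
                                                seed = config$seed))
    utils::write.csv(prof$classes,
                     file.path(config$out_dir, "mortality_profile.csv"),
                     row.names = FALSE)
    summary$mortality <- list(n_total = mc$n_total,
                              classes_present = mc$labels[mc$counts > 0])
    results$mortality <- prof
  }

  # --- report --------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(serialise_config(config), cfg_path)
  summary$config_hash <- config_hash(config)
  sum_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(sprintf("herdseason %s", summary$package_version),
               sprintf("seed: %s", config$seed),
               sprintf("config hash: %s", summary$config_hash),
               sprintf("stages: %s", paste(names(results), collapse = ", "))),
             file.path(config$out_dir, "run.log"))
  invisible(c(results, list(summary = summary, summary_path = sum_path)))
}

serialise_config <- function(config) {
  lapply(config, function(v) {
    if (is.function(v)) NULL
    else if (inherits(v, "maldi_spectrum")) v$specimen_id
    else if (is.list(v) && !is.data.frame(v) &&
             all(vapply(v, inherits, TRUE, "maldi_spectrum"))) {
      vapply(v, function(s) s$specimen_id, "")
    }
    else if (is.list(v) && !is.data.frame(v) &&
             all(vapply(v, inherits, TRUE, "tooth_sequence"))) {
      vapply(v, function(s) attr(s, "specimen_id"), "")
    }
    else if (is.data.frame(v)) as.list(v)
    else unclass(v)
  })
}

config_hash <- function(config) {
  # dependency-free content hash: cheap polynomial rolling hash over the
  # serialised config (auditing aid, not cryptographic). The output path is
  # excluded so identical analyses hash identically wherever they are run.
  cfg <- serialise_config(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
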