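# ZooMS: collagen peptide-mass fingerprint processing and Ovis/Capra calls.
#
# Sheep and goat COL1a2 fingerprints are near-identical except for the
# COL1a2 757(+16) peptide -- m/z 3017.4 / 3033.4 in sheep versus 3077.4 /
# 3093.4 in goat -- and the COL1a2 375 masses (1154, 2028, 2044), which are
# caprine-informative but not assigned per taxon here, so they support but
# never decide a call.

#' COL1a2 marker panel for caprine identification
#'
#' @return Object of class `marker_panel`: data frame `marker`, `taxon`,
#'   `mz`, `decisive`.
#' @export
caprine_marker_panel <- function() {
  structure(data.frame(
    marker = c(rep("COL1a2 757(+16)", 4), rep("COL1a2 375", 3)),
    taxon = c("Ovis", "Ovis", "Capra", "Capra", rep("Caprinae", 3)),
    mz = c(3017.4, 3033.4, 3077.4, 3093.4, 1154, 2028, 2044),
    decisive = c(rep(TRUE, 4), rep(FALSE, 3)),
    stringsAsFactors = FALSE
  ), class = c("marker_panel", "data.frame"))
}

#' MALDI-ToF spectrum container
#'
#' @param mz Strictly increasing m/z values (Da).
#' @param intensity Non-negative intensities (arbitrary units).
#' @param specimen_id Specimen identifier.
#' @param metadata Optional free-text acquisition metadata.
#' @return Object of class `maldi_spectrum`.
#' @export
maldi_spectrum <- function(mz, intensity, specimen_id = "unknown", metadata = "") {
  if (length(mz) != length(intensity)) stop("mz/intensity lengths differ", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) stop("m/z must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 specimen_id = as.character(specimen_id), metadata = metadata),
            class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("MALDI spectrum %s: %d points, m/z %.1f-%.1f\n",
              x$specimen_id, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a MALDI spectrum from disk
#'
#' Two-column whitespace/CSV text (m/z, intensity; `#` comments allowed) or
#' mzML (read via the mzR package when installed).
#'
#' @param path File path; format decided by extension (`.mzML` vs text).
#' @param specimen_id Defaults to the file name without extension.
#' @return A [maldi_spectrum()].
#' @export
read_spectrum <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  if (is.null(specimen_id)) specimen_id <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    return(maldi_spectrum(pk[, 1], pk[, 2], specimen_id, metadata = path))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = grepl("[A-Za-z]", first), sep = sep,
                          comment.char = "#")
  maldi_spectrum(df[[1]], df[[2]], specimen_id, metadata = path)
}

#' Spectral processing parameters
#'
#' Defaults mirror a standard ZooMS workflow: baseline correction
#' (precision 15, relative offset 25), Savitzky-Golay smoothing (0.3 m/z
#' window, 2 cycles) and peak picking at signal-to-noise 3.5 with a picking
#' height of 75 (the percent of apex height above which points enter the
#' centroid).
#'
#' @param baseline_precision Number of baseline segments across the m/z
#'   range; higher follows the baseline more closely. Default 15.
#' @param baseline_rel_offset Percent of the local noise level added to the
#'   interpolated baseline before subtraction. Default 25.
#' @param sg_window_mz Savitzky-Golay window in m/z units. Default 0.3.
#' @param sg_cycles Smoothing passes. Default 2.
#' @param snr_threshold Minimum signal-to-noise for a retained peak.
#'   Default 3.5.
#' @param picking_height Percent of apex height delimiting the points used
#'   for centroid refinement. Default 75.
#' @return List of class `maldi_params`.
#' @export
maldi_params <- function(baseline_precision = 15, baseline_rel_offset = 25,
                         sg_window_mz = 0.3, sg_cycles = 2,
                         snr_threshold = 3.5, picking_height = 75) {
  structure(list(baseline_precision = baseline_precision,
                 baseline_rel_offset = baseline_rel_offset,
                 sg_window_mz = sg_window_mz, sg_cycles = sg_cycles,
                 snr_threshold = snr_threshold, picking_height = picking_height),
            class = "maldi_params")
}

# segment-percentile baseline: low quantile per segment, linearly
# interpolated across the spectrum, then shifted by a fraction of the noise
estimate_baseline <- function(mz, intensity, precision, rel_offset, noise) {
  n <- length(mz)
  brks <- unique(round(seq(1L, n, length.out = max(precision, 2L) + 1L)))
  anchors_x <- anchors_y <- numeric(length(brks) - 1L)
  for (i in seq_len(length(brks) - 1L)) {
    idx <- brks[i]:brks[i + 1L]
    anchors_x[i] <- mean(mz[idx])
    anchors_y[i] <- stats::quantile(intensity[idx], 0.10, names = FALSE)
  }
  bl <- stats::approx(anchors_x, anchors_y, xout = mz, rule = 2)$y
  bl + rel_offset / 100 * noise
}

# robust noise level: MAD about the median of the (baseline-corrected)
# signal. Peaks are sparse, so the MAD tracks the noise floor; unlike a
# successive-difference estimator it stays correct when the noise is
# correlated across neighbouring points, as accumulated profile spectra are.
estimate_noise <- function(intensity) {
  stats::mad(intensity, center = stats::median(intensity))
}

#' Process a MALDI spectrum into a peak list
#'
#' Baseline-subtracts (segment-percentile baseline plus a relative offset),
#' smooths (Savitzky-Golay, window converted from m/z to an odd point
#' count, repeated cycles) and picks peaks as local maxima above the
#' signal-to-noise threshold, with intensity-weighted centroid refinement
#' over the points above `picking_height` percent of the apex.
#'
#' @param spec A [maldi_spectrum()].
#' @param params A [maldi_params()].
#' @return Object of class `maldi_peaklist`: data frame `mz`, `intensity`,
#'   `snr`, with the specimen id as attribute.
#' @export
process_spectrum <- function(spec, params = maldi_params()) {
  stopifnot(inherits(spec, "maldi_spectrum"))
  n <- length(spec$mz)
  if (n < 100L) stop("spectrum too short (need >= 100 points)", call. = FALSE)
  step <- stats::median(diff(spec$mz))
  noise0 <- estimate_noise(spec$intensity)
  y <- spec$intensity -
    estimate_baseline(spec$mz, spec$intensity, params$baseline_precision,
                      params$baseline_rel_offset, noise0)
  w <- round(params$sg_window_mz / step)
  if (w %% 2 == 0) w <- w + 1L
  if (w >= 5L) {
    if (w >= n) stop("spectrum shorter than smoothing window", call. = FALSE)
    for (i in seq_len(params$sg_cycles)) {
      y <- signal::sgolayfilt(y, p = 2, n = w)
    }
  }
  noise <- estimate_noise(y)
  if (noise <= 0) noise <- max(stats::sd(y), .Machine$double.eps)

  # local maxima above the S/N floor
  cand <- which(y[c(-1, -n)] > y[c(-(n - 1), -n)] & y[c(-1, -n)] >= y[c(-1, -2)]) + 1L
  cand <- cand[y[cand] / noise >= params$snr_threshold]
  if (!length(cand)) {
    return(structure(data.frame(mz = numeric(0), intensity = numeric(0),
                                snr = numeric(0)),
                     specimen_id = spec$specimen_id,
                     class = c("maldi_peaklist", "data.frame")))
  }
  # collapse candidates closer than the smoothing window to the strongest
  ord <- cand[order(-y[cand])]
  keepers <- integer(0)
  min_sep <- max(w, 3L) * step
  for (i in ord) {
    if (!length(keepers) || all(abs(spec$mz[i] - spec$mz[keepers]) >= min_sep)) {
      keepers <- c(keepers, i)
    }
  }
  keepers <- sort(keepers)
  cent <- vapply(keepers, function(i) {
    apex <- y[i]
    thr <- params$picking_height / 100 * apex
    lo <- i; while (lo > 1L && y[lo - 1L] >= thr && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] >= thr && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    idx <- lo:hi
    sum(spec$mz[idx] * y[idx]) / sum(y[idx])
  }, 0)
  out <- data.frame(mz = cent, intensity = y[keepers], snr = y[keepers] / noise)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, specimen_id = spec$specimen_id,
            class = c("maldi_peaklist", "data.frame"))
}

#' Call Ovis vs Capra from a peak list
#'
#' Matches picked peaks to the marker panel (nearest peak within the mass
#' tolerance). The call is `Ovis` iff at least one decisive Ovis marker
#' matches and no decisive Capra marker does (and symmetrically);
#' `Ambiguous` when both genera match; `Indeterminate` when neither does.
#' Non-decisive (caprine-informative) markers are reported as supporting
#' evidence only.
#'
#' @param peaks A [process_spectrum()] peak list.
#' @param panel A [caprine_marker_panel()]-style data frame.
#' @param tolerance Mass tolerance (Da), default 0.5 (linear-mode MALDI).
#' @return Object of class `taxon_call`: list with `specimen_id`, `call`,
#'   and `evidence` (per-marker observed m/z, mass error, S/N).
#' @export
call_taxon <- function(peaks, panel = caprine_marker_panel(), tolerance = 0.5) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (!nrow(panel)) stop("empty marker panel", call. = FALSE)
  ev <- panel
  ev$observed_mz <- NA_real_; ev$mass_error <- NA_real_; ev$snr <- NA_real_
  ev$matched <- FALSE
  if (nrow(peaks)) {
    for (i in seq_len(nrow(ev))) {
      d <- abs(peaks$mz - ev$mz[i])
      j <- which.min(d)
      if (d[j] <= tolerance) {
        ev$observed_mz[i] <- peaks$mz[j]
        ev$mass_error[i] <- peaks$mz[j] - ev$mz[i]
        ev$snr[i] <- peaks$snr[j]
        ev$matched[i] <- TRUE
      }
    }
  }
  ovis <- any(ev$matched & ev$decisive & ev$taxon == "Ovis")
  capra <- any(ev$matched & ev$decisive & ev$taxon == "Capra")
  call <- if (ovis && capra) "Ambiguous" else if (ovis) "Ovis"
          else if (capra) "Capra" else "Indeterminate"
  structure(list(specimen_id = attr(peaks, "specimen_id") %||% "unknown",
                 call = call, evidence = ev, tolerance = tolerance),
            class = "taxon_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.taxon_call <- function(x, ...) {
  cat(sprintf("ZooMS call for %s: %s\n", x$specimen_id, x$call))
  m <- x$evidence[x$evidence$matched, c("marker", "taxon", "mz", "observed_mz", "snr")]
  if (nrow(m)) print(m, row.names = FALSE) else cat("  no markers matched\n")
  invisible(x)
}

#' Batch ZooMS identification
#'
#' Processes a set of spectra (a directory of files, file paths, or
#' in-memory [maldi_spectrum()] objects) and tabulates the taxon calls.
#' Unreadable files are skipped with a warning and reported in the output.
#'
#' @param spectra Directory path, character vector of files, or list of
#'   `maldi_spectrum` objects.
#' @param panel Marker panel.
#' @param params Processing parameters.
#' @param tolerance Mass tolerance (Da).
#' @return List `calls` (data frame `specimen_id`, `call`), `summary`
#'   (counts by call), `failed` (character vector of unreadable inputs).
#' @export
batch_report <- function(spectra, panel = caprine_marker_panel(),
                         params = maldi_params(), tolerance = 0.5) {
  if (is.character(spectra) && length(spectra) == 1L && dir.exists(spectra)) {
    spectra <- list.files(spectra, full.names = TRUE)
  }
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  if (is.character(spectra)) spectra <- as.list(sort(spectra))
  failed <- character(0)
  rows <- list()
  for (s in spectra) {
    sp <- if (inherits(s, "maldi_spectrum")) s else {
      tryCatch(read_spectrum(s), error = function(e) {
        warning(sprintf("skipping unreadable spectrum %s: %s", s, conditionMessage(e)))
        NULL
      })
    }
    if (is.null(sp)) { failed <- c(failed, as.character(s)); next }
    tc <- call_taxon(process_spectrum(sp, params), panel, tolerance)
    rows[[length(rows) + 1L]] <- data.frame(specimen_id = tc$specimen_id,
                                            call = tc$call,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no readable spectra", call. = FALSE)
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$specimen_id), , drop = FALSE]
  rownames(calls) <- NULL
  lv <- c("Ovis", "Capra", "Ambiguous", "Indeterminate")
  list(calls = calls,
       summary = table(factor(calls$call, levels = lv)),
       failed = failed)
}
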