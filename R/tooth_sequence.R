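#' Intra-tooth isotope sequence
#'
#' Container for sequential enamel samples drilled along one tooth crown of
#' one specimen. Distances are measured in mm from the enamel--root junction
#' (ERJ), increasing towards the occlusal surface; isotope values are in
#' per-mille on the VPDB scale. Rows supplied in either direction are
#' canonically re-sorted by distance.
#'
#' @param specimen_id Character specimen identifier.
#' @param distance_mm Numeric vector of sampling positions, mm from the ERJ
#'   (all >= 0).
#' @param d18O Numeric vector of oxygen isotope values (permil VPDB).
#' @param d13C Optional numeric vector of carbon isotope values (permil
#'   VPDB); `NA` allowed when carbon was not measured.
#' @param taxon One of `"Ovis"`, `"Capra"`, `"OvisCapra"`.
#' @param tooth Free-text tooth label (default `"mandibular M2"`).
#' @param erj_present Logical, whether the ERJ is preserved so that distances
#'   are anchored to a true developmental reference point.
#' @param lab_flag Optional per-sample character annotations.
#'
#' @return An object of class `tooth_sequence`: a data frame with columns
#'   `distance_mm`, `d18O`, `d13C`, `lab_flag` and attributes `specimen_id`,
#'   `taxon`, `tooth`, `erj_present`.
#' @examples
#' ts <- tooth_sequence("demo", distance_mm = seq(0, 30, 2),
#'                      d18O = -5 + 3 * cos(2 * pi * (seq(0, 30, 2) - 10) / 25))
#' ts
#' @export
tooth_sequence <- function(specimen_id, distance_mm, d18O, d13C = NULL,
                           taxon = c("OvisCapra", "Ovis", "Capra"),
                           tooth = "mandibular M2", erj_present = TRUE,
                           lab_flag = NULL) {
  taxon <- match.arg(taxon)
  n <- length(distance_mm)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (length(d18O) != n) stop("d18O and distance_mm lengths differ", call. = FALSE)
  if (is.null(d13C)) d13C <- rep(NA_real_, n)
  if (length(d13C) != n) stop("d13C and distance_mm lengths differ", call. = FALSE)
  if (is.null(lab_flag)) lab_flag <- rep("", n)
  stop_if_not_finite(distance_mm, "distance_mm")
  if (any(distance_mm < 0)) stop("distances must be >= 0 mm from the ERJ", call. = FALSE)
  stop_if_not_finite(d18O, "d18O")
  if (any(!is.finite(d13C) & !is.na(d13C))) stop("non-finite values in d13C", call. = FALSE)

  ord <- order(distance_mm)
  x <- data.frame(distance_mm = as.numeric(distance_mm[ord]),
                  d18O = as.numeric(d18O[ord]),
                  d13C = as.numeric(d13C[ord]),
                  lab_flag = as.character(lab_flag[ord]),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$distance_mm)) {
    stop("duplicated sampling distances; distances must be strictly increasing",
         call. = FALSE)
  }
  structure(x,
            specimen_id = as.character(specimen_id),
            taxon = taxon, tooth = tooth,
            erj_present = isTRUE(erj_present),
            class = c("tooth_sequence", "data.frame"))
}

#' @export
print.tooth_sequence <- function(x, ...) {
  cat(sprintf("Intra-tooth isotope sequence: %s (%s, %s)\n",
              attr(x, "specimen_id"), attr(x, "taxon"), attr(x, "tooth")))
  cat(sprintf("  %d samples over %.1f-%.1f mm from ERJ; ERJ %s\n",
              nrow(x), min(x$distance_mm), max(x$distance_mm),
              if (attr(x, "erj_present")) "present" else "missing"))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read intra-tooth sequences from a delimited file
#'
#' Expects long-format columns `specimen_id`, `distance_mm`, `d18O` and
#' optionally `d13C`, `taxon`, `tooth`, `erj_present`. Returns one
#' [tooth_sequence()] per specimen.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the header line).
#' @return Named list of `tooth_sequence` objects.
#' @export
read_tooth_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("specimen_id", "distance_mm", "d18O")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
                         call. = FALSE)
  out <- lapply(split(df, df$specimen_id), function(d) {
    tooth_sequence(
      specimen_id = d$specimen_id[1],
      distance_mm = d$distance_mm,
      d18O = d$d18O,
      d13C = if ("d13C" %in% names(d)) d$d13C else NULL,
      taxon = if ("taxon" %in% names(d)) d$taxon[1] else "OvisCapra",
      tooth = if ("tooth" %in% names(d)) d$tooth[1] else "mandibular M2",
      erj_present = if ("erj_present" %in% names(d)) as.logical(d$erj_present[1]) else TRUE
    )
  })
  out[order(names(out))]
}

# interior clear extremum test: the global max (or min) must sit at an
# interior sample and the series must fall away from it by at least the
# measurement precision on BOTH sides (side minima, not just the immediate
# neighbours, so the test is robust to the apex landing between samples).
has_clear_extremum <- function(y, precision, which = c("max", "min")) {
  which <- match.arg(which)
  n <- length(y)
  if (n < 3L) return(FALSE)
  if (which == "min") y <- -y
  i <- which.max(y)
  if (i == 1L || i == n) return(FALSE)
  (y[i] - min(y[seq_len(i - 1L)]) >= precision) &&
    (y[i] - min(y[seq.int(i + 1L, n)]) >= precision)
}

#' Screening rules for cosine modelling
#'
#' @param min_range Minimum intra-tooth d18O range (permil) below which a
#'   sequence is flagged `low_amplitude`. Default 2.
#' @param precision Analytical measurement precision for d18O (permil); a
#'   clear maximum/minimum must stand proud of its neighbours by at least
#'   this much. Default 0.12.
#' @param min_samples Minimum number of samples for fitting. Default 4.
#' @param min_r2 Minimum variance explained by a quick cosine profile fit for
#'   the sequence to count as sinusoidal. Default 0.5.
#' @param require_erj Whether a missing enamel-root junction excludes the
#'   specimen. Default TRUE.
#' @return A list of thresholds used by [screen_sequence()].
#' @export
screening_rules <- function(min_range = 2, precision = 0.12, min_samples = 4L,
                            min_r2 = 0.5, require_erj = TRUE) {
  list(min_range = min_range, precision = precision,
       min_samples = as.integer(min_samples), min_r2 = min_r2,
       require_erj = isTRUE(require_erj))
}

#' Screen a tooth sequence for cosine-model eligibility
#'
#' Sequences with very low amplitude of variation, no sinusoidal pattern, no
#' clear interior maximum (or minimum), too few samples, or a missing
#' enamel-root junction are excluded from seasonality modelling.
#'
#' @param seq A [tooth_sequence()].
#' @param rules Thresholds from [screening_rules()].
#' @return A list with `eligible` (logical) and `reasons` (character vector
#'   drawn from `low_amplitude`, `no_sinusoid`, `no_clear_max`,
#'   `no_clear_min`, `missing_erj`, `too_few_samples`). A missing clear
#'   minimum alone does not exclude a specimen, but callers should treat the
#'   resulting birth-season estimate as tentative.
#' @examples
#' x <- seq(0, 30, 1.5)
#' ts <- tooth_sequence("ok", x, -5 + 4 * cos(2 * pi * (x - 10) / 25))
#' screen_sequence(ts)
#' @export
screen_sequence <- function(seq, rules = screening_rules()) {
  stopifnot(inherits(seq, "tooth_sequence"))
  if (nrow(seq) == 0L) stop("empty sequence", call. = FALSE)
  y <- seq$d18O
  reasons <- character(0)
  if (nrow(seq) < rules$min_samples) reasons <- c(reasons, "too_few_samples")
  if (rules$require_erj && !attr(seq, "erj_present")) reasons <- c(reasons, "missing_erj")
  rng <- diff(range(y))
  low_amp <- rng < rules$min_range
  if (low_amp) reasons <- c(reasons, "low_amplitude")
  clear_max <- has_clear_extremum(y, rules$precision, "max")
  clear_min <- has_clear_extremum(y, rules$precision, "min")
  if (!clear_max) reasons <- c(reasons, "no_clear_max")
  if (!clear_min) reasons <- c(reasons, "no_clear_min")
  # sinusoidality: degenerate variation, or a quick profiled cosine fit
  # explaining too little variance
  no_sin <- low_amp
  if (!no_sin && nrow(seq) >= rules$min_samples) {
    pf <- profile_cosine(seq$distance_mm, y)
    r2 <- 1 - pf$sse / sum((y - mean(y))^2)
    no_sin <- is.finite(r2) && r2 < rules$min_r2
  }
  if (no_sin) reasons <- c(reasons, "no_sinusoid")
  excl <- setdiff(reasons, "no_clear_min")  # tentative, not exclusionary
  list(eligible = length(excl) == 0L, reasons = reasons)
}

#' Intra-tooth summary statistics
#'
#' Minimum, maximum, range (max - min) and half-range ((max - min)/2) of each
#' measured isotope, plus whether the optima are identifiable (an interior
#' clear maximum and minimum). Both the full range and the half-range are
#' reported because "amplitude" is used in both senses in the literature.
#'
#' @param seq A [tooth_sequence()].
#' @param precision Measurement precision (permil) used for the clear-optima
#'   test. Default 0.12.
#' @return Data frame with one row per isotope: `isotope`, `n`, `min`, `max`,
#'   `range`, `half_range`, `optima_identifiable`.
#' @export
intra_tooth_summary <- function(seq, precision = 0.12) {
  stopifnot(inherits(seq, "tooth_sequence"))
  if (nrow(seq) < 2L) stop("at least two samples required", call. = FALSE)
  one <- function(y, iso) {
    y <- y[!is.na(y)]
    if (length(y) < 2L) return(NULL)
    cmx <- has_clear_extremum(y, precision, "max")
    cmn <- has_clear_extremum(y, precision, "min")
    data.frame(isotope = iso, n = length(y), min = min(y), max = max(y),
               range = diff(range(y)), half_range = diff(range(y)) / 2,
               clear_max = cmx, clear_min = cmn,
               optima_identifiable = cmx || cmn,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(seq$d18O, "d18O"), one(seq$d13C, "d13C"))
  rownames(out) <- NULL
  out
}
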