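#' Configuration for the C3/C4 two-end-member mixing model
#'
#' End-members are the expected tissue d13C for a pure C3 and a pure C4
#' diet. Defaults follow regional Caucasus plant surveys: modern plant means
#' are corrected by +1.5 permil for the fossil-fuel (Suess) effect, then
#' shifted into tissue space by a +14.1 permil diet-to-enamel enrichment
#' factor for ruminants, or a +5 permil diet-to-collagen offset. The
#' resulting defaults are -11.58/+4.18 permil in enamel and -20.3/-6.3
#' permil in collagen. Values around -6.7 permil in enamel mark the extreme
#' enrichment achievable on purely water-stressed C3 plants; enamel values
#' above it therefore demand a genuine C4 component.
#'
#' @param suess_correction Fossil-fuel correction added to modern plant
#'   values (permil). Default +1.5.
#' @param enamel_enrichment_epsilon Diet-to-enamel enrichment (permil).
#'   Default +14.1.
#' @param collagen_diet_offset Diet-to-collagen offset (permil). Default +5.
#' @param enamel_c3_endmember,enamel_c4_endmember Enamel end-members
#'   (permil), defaults -11.58 (sd 3.00) and +4.18 (sd 1.17).
#' @param enamel_c3_sd,enamel_c4_sd Reported spreads of the end-members.
#' @param collagen_c3_endmember,collagen_c4_endmember Collagen end-members
#'   (permil), defaults -20.3 and -6.3.
#' @param water_stressed_c3_limit_enamel Enamel d13C ceiling for a purely
#'   water-stressed C3 diet (permil). Default -6.7.
#' @param enrichment_form `"linear_addition"` (add epsilon) or
#'   `"alpha_exact"` (exact fractionation
#'   `(d + 1000) * (1 + eps/1000) - 1000`). The two differ by < 0.5 permil
#'   for plant values in \[-30, -10\] permil.
#' @return A list of class `mixing_config`.
#' @export
mixing_config <- function(suess_correction = 1.5,
                          enamel_enrichment_epsilon = 14.1,
                          collagen_diet_offset = 5.0,
                          enamel_c3_endmember = -11.58, enamel_c3_sd = 3.00,
                          enamel_c4_endmember = 4.18, enamel_c4_sd = 1.17,
                          collagen_c3_endmember = -20.3,
                          collagen_c4_endmember = -6.3,
                          water_stressed_c3_limit_enamel = -6.7,
                          enrichment_form = c("linear_addition", "alpha_exact")) {
  enrichment_form <- match.arg(enrichment_form)
  if (enamel_c4_endmember <= enamel_c3_endmember ||
      collagen_c4_endmember <= collagen_c3_endmember) {
    stop("C4 end-member must exceed C3 end-member in every tissue", call. = FALSE)
  }
  if (enamel_enrichment_epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(
    suess_correction = suess_correction,
    enamel_enrichment_epsilon = enamel_enrichment_epsilon,
    collagen_diet_offset = collagen_diet_offset,
    enamel_c3_endmember = enamel_c3_endmember, enamel_c3_sd = enamel_c3_sd,
    enamel_c4_endmember = enamel_c4_endmember, enamel_c4_sd = enamel_c4_sd,
    collagen_c3_endmember = collagen_c3_endmember,
    collagen_c4_endmember = collagen_c4_endmember,
    water_stressed_c3_limit_enamel = water_stressed_c3_limit_enamel,
    enrichment_form = enrichment_form
  ), class = "mixing_config")
}

#' Read a mixing configuration from a YAML file
#'
#' The package ships its default configuration at
#' `system.file("extdata", "mixing_config.yaml", package = "herdseason")`.
#'
#' @param path YAML file with [mixing_config()] fields (missing fields fall
#'   back to the defaults).
#' @return A [mixing_config()].
#' @export
read_mixing_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mixing_config))
  do.call(mixing_config, vals[intersect(names(vals), known)])
}

endmembers <- function(tissue, cfg) {
  if (tissue == "enamel") c(cfg$enamel_c3_endmember, cfg$enamel_c4_endmember)
  else c(cfg$collagen_c3_endmember, cfg$collagen_c4_endmember)
}

#' Derive a tissue end-member from modern plant d13C values
#'
#' Takes the mean (and sd) of modern plant d13C values, applies the Suess
#' correction, and transforms into tissue space: for enamel either simple
#' addition of the enrichment factor or the exact fractionation form; for
#' collagen the diet-to-collagen offset.
#'
#' @param plant_d13C Numeric vector of modern plant d13C values (permil).
#' @param tissue `"enamel"` or `"collagen"`.
#' @param cfg A [mixing_config()].
#' @return List with `mean` and `sd` (sd is `NA` for a single value; the
#'   additive transforms leave it unchanged, `alpha_exact` rescales it by
#'   `1 + eps/1000`).
#' @examples
#' endmember_from_plants(-27.18, "enamel")$mean  # -11.58
#' @export
endmember_from_plants <- function(plant_d13C, tissue = c("enamel", "collagen"),
                                  cfg = mixing_config()) {
  tissue <- match.arg(tissue)
  if (length(plant_d13C) == 0L) stop("no plant values supplied", call. = FALSE)
  stop_if_not_finite(plant_d13C, "plant_d13C")
  m <- mean(plant_d13C) + cfg$suess_correction
  s <- if (length(plant_d13C) > 1L) stats::sd(plant_d13C) else NA_real_
  if (tissue == "enamel") {
    if (cfg$enrichment_form == "alpha_exact") {
      f <- 1 + cfg$enamel_enrichment_epsilon / 1000
      m <- (m + 1000) * f - 1000
      s <- s * f
    } else {
      m <- m + cfg$enamel_enrichment_epsilon
    }
  } else {
    m <- m + cfg$collagen_diet_offset
  }
  list(mean = m, sd = s)
}

#' Percent C4 diet from a tissue d13C value
#'
#' Linear two-end-member interpolation between the pure-C3 and pure-C4
#' cut-offs of the given tissue. Raw interpolations outside \[0, 100\] are
#' clipped and flagged rather than erroring, since measurement noise can
#' push values slightly past an end-member.
#'
#' @param d13C Numeric vector of tissue d13C values (permil VPDB).
#' @param tissue `"enamel"` or `"collagen"`.
#' @param cfg A [mixing_config()].
#' @return Data frame (class `mixing_result`): `d13C`, `tissue`, `pct_C4`,
#'   `pct_C3`, `clipped`, and for enamel
#'   `exceeds_water_stressed_c3_limit`.
#' @examples
#' pct_c4(-3.70, "enamel")$pct_C4   # 50: midpoint of (-11.58, 4.18)
#' pct_c4(-19.1, "collagen")$pct_C4 # about 8.6
#' @export
pct_c4 <- function(d13C, tissue = c("enamel", "collagen"), cfg = mixing_config()) {
  tissue <- match.arg(tissue)
  stop_if_not_finite(d13C, "d13C")
  em <- endmembers(tissue, cfg)
  if (em[2] == em[1]) stop("degenerate end-members", call. = FALSE)
  raw <- 100 * (d13C - em[1]) / (em[2] - em[1])
  p4 <- pmin(pmax(raw, 0), 100)
  out <- data.frame(d13C = d13C, tissue = tissue, pct_C4 = p4,
                    pct_C3 = 100 - p4,
                    clipped = raw < 0 | raw > 100,
                    stringsAsFactors = FALSE)
  if (tissue == "enamel") {
    out$exceeds_water_stressed_c3_limit <- d13C > cfg$water_stressed_c3_limit_enamel
  }
  class(out) <- c("mixing_result", "data.frame")
  out
}

#' Inverse mixing: tissue d13C from a known C4 fraction
#'
#' Used by the synthetic-data generator and the inversion property tests.
#'
#' @param pct Percent C4 in \[0, 100\].
#' @inheritParams pct_c4
#' @return Numeric d13C (permil).
#' @export
d13c_from_pct_c4 <- function(pct, tissue = c("enamel", "collagen"),
                             cfg = mixing_config()) {
  tissue <- match.arg(tissue)
  em <- endmembers(tissue, cfg)
  em[1] + pct / 100 * (em[2] - em[1])
}

#' Seasonal C4 diet summary along a fitted tooth sequence
#'
#' Labels every increment of a tooth sequence with a season derived from the
#' fitted d18O phase (not from raw extremes): increments within a quarter
#' cycle of the modelled d18O maximum are "summer", within a quarter cycle
#' of the minimum "winter", the rest "transitional". Maximum d18O is read as
#' the summer signal and minimum d18O as the winter signal. Per-season mean
#' and range of the percent-C4 diet are then reported.
#'
#' @param fit A converged [fit_seasonal_cosine()] for the specimen's d18O.
#' @param seq The matching [tooth_sequence()] with measured `d13C`.
#' @param cfg A [mixing_config()]; enamel end-members are used.
#' @return List with `per_sample` (distance, season, pct_C4) and
#'   `per_season` (season, n, mean, min, max of pct_C4).
#' @export
classify_seasonal_diet <- function(fit, seq, cfg = mixing_config()) {
  stopifnot(inherits(fit, "seasonal_fit"), inherits(seq, "tooth_sequence"))
  if (!isTRUE(fit$converged)) stop("no converged d18O fit", call. = FALSE)
  keep <- is.finite(seq$d13C)
  x <- seq$distance_mm[keep]
  if (!length(x)) stop("no d13C measurements in sequence", call. = FALSE)
  phase <- (2 * pi * (x - fit$x0) / fit$X) %mod% (2 * pi)  # 0 at d18O max
  season <- ifelse(pmin(phase, 2 * pi - phase) <= pi / 4, "summer",
                   ifelse(abs(phase - pi) <= pi / 4, "winter", "transitional"))
  p4 <- pct_c4(seq$d13C[keep], "enamel", cfg)$pct_C4
  per_sample <- data.frame(distance_mm = x, season = season, pct_C4 = p4,
                           stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(per_sample, per_sample$season), function(d) {
    data.frame(season = d$season[1], n = nrow(d), mean_pct_C4 = mean(d$pct_C4),
               min_pct_C4 = min(d$pct_C4), max_pct_C4 = max(d$pct_C4),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_sample = per_sample, per_season = agg)
}
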