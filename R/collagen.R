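#' Atomic C:N ratio of collagen
#'
#' `(pctC / 12.011) / (pctN / 14.007)`. Well-preserved collagen falls near
#' 2.9--3.6.
#'
#' @param pctC,pctN Weight-percent carbon and nitrogen (> 0).
#' @return Numeric atomic ratio (full precision; round at the report layer).
#' @examples
#' cn_atomic(45, 16)  # 3.28
#' @export
cn_atomic <- function(pctC, pctN) {
  if (any(!is.finite(pctC)) || any(!is.finite(pctN)) ||
      any(pctC <= 0) || any(pctN <= 0)) {
    stop("pctC and pctN must be positive", call. = FALSE)
  }
  (pctC / 12.011) / (pctN / 14.007)
}

#' Collagen quality control
#'
#' A sample passes when its atomic C:N ratio lies within the preservation
#' window and its collagen yield meets the minimum.
#'
#' @param samples Data frame with columns `d13C`, `d15N`, `pctC`, `pctN`,
#'   `yield` (and optionally `specimen_id`, `taxon`).
#' @param cn_window Acceptable C:N window, default `c(2.9, 3.6)`.
#' @param min_yield Minimum collagen yield (wt%), default 1.
#' @return The input with added `cn_atomic` and `qc_pass` columns.
#' @export
collagen_qc <- function(samples, cn_window = c(2.9, 3.6), min_yield = 1) {
  need <- c("d13C", "d15N", "pctC", "pctN", "yield")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
                         call. = FALSE)
  samples$cn_atomic <- cn_atomic(samples$pctC, samples$pctN)
  samples$qc_pass <- samples$cn_atomic >= cn_window[1] &
    samples$cn_atomic <= cn_window[2] & samples$yield >= min_yield
  samples
}

#' Descriptive summary of an isotope series
#'
#' @param values Numeric vector (permil).
#' @return List `n`, `mean`, `sd` (sample sd, n-1 denominator; `NA` for
#'   n = 1), `min`, `max`.
#' @export
iso_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values", call. = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       min = min(values), max = max(values))
}

#' Pearson and Spearman correlation with p-values
#'
#' Pearson's r with its t-distribution p-value and Spearman's rho with the
#' standard approximation, plus an optional seeded permutation p-value for
#' the Pearson statistic (useful at small n).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param n_perm Number of permutations for the optional exact-style p
#'   (0 = skip).
#' @param seed Seed for the permutation draw.
#' @return List `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`, and
#'   `perm_p` when requested.
#' @export
correlate <- function(x, y, n_perm = 0L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables; correlation undefined",
         call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  out <- list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
              spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  if (n_perm > 0L) {
    r0 <- abs(out$pearson_r)
    out$perm_p <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(x, sample(y))) >= r0 - 1e-12
      }, TRUE))
      (hits + 1) / (n_perm + 1)
    })
  }
  out
}

#' IQR outlier screening
#'
#' Tukey fences: values outside `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR` are
#' flagged. Quartiles use linear interpolation of order statistics
#' (`quantile` type 7) -- stated because the outlier set depends on the
#' convention. The rule is single-pass: fences are computed once on the full
#' input, not recomputed on the kept set.
#'
#' @param values Numeric vector, n >= 4.
#' @param k Fence multiplier, default 1.5.
#' @return List `kept`, `flagged`, `fences` (lower, upper).
#' @export
iqr_outliers <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values; no outlier screening applied")
    return(list(kept = values, flagged = numeric(0), fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], flagged = values[out], fences = fences)
}

#' 95% confidence ellipse of a bivariate sample
#'
#' Ellipse from the sample mean and covariance, scaled by the chi-square
#' quantile with 2 degrees of freedom (5.991 at level 0.95). Returned as
#' parameters, not graphics.
#'
#' @param xy Two-column matrix or data frame of paired observations, n >= 3.
#' @param level Coverage level, default 0.95.
#' @return List `center` (length 2), `semi_axes` (major, minor), `rotation`
#'   (radians, direction of the major axis), `cov`, `level`.
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("xy must have two columns", call. = FALSE)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  S <- stats::cov(xy)
  if (abs(det(S)) < 1e-12 * max(abs(S))^2) stop("singular covariance", call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  list(center = colMeans(xy),
       semi_axes = sqrt(q * e$values),
       rotation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S, level = level)
}

#' One-way ANOVA
#'
#' Classical one-way fixed-effects ANOVA. Degenerate input with zero
#' between- and within-group variance returns `F = 0, p = 1` rather than
#' erroring.
#'
#' @param groups List of numeric vectors, or a numeric vector plus `g` group
#'   labels.
#' @param g Optional grouping vector when `groups` is a single vector.
#' @return List `F`, `p`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  if (k < 2L || any(n < 1L) || sum(n) <= k) {
    stop("need >= 2 groups and total n > number of groups", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  if (diff(range(y)) == 0) {
    return(list(F = 0, p = 1, df_between = k - 1L, df_within = sum(n) - k))
  }
  # zero within-group variance with distinct means: F degenerates to Inf
  if (all(vapply(groups, function(v) diff(range(v)) == 0, TRUE))) {
    return(list(F = Inf, p = 0, df_between = k - 1L, df_within = sum(n) - k))
  }
  f <- factor(rep(seq_len(k), n))
  a <- stats::anova(stats::lm(y ~ f))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df_between = a$Df[1], df_within = a$Df[2])
}
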