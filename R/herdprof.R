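#' Payne age classes for caprines
#'
#' Ordered mandibular wear classes A--I with their conventional age spans.
#'
#' @return Data frame `class`, `age_span`.
#' @export
payne_classes <- function() {
  data.frame(class = LETTERS[1:9],
             age_span = c("0-2 mo", "2-6 mo", "6-12 mo", "1-2 y", "2-3 y",
                          "3-4 y", "4-6 y", "6-8 y", "8-10 y"),
             stringsAsFactors = FALSE)
}

#' Per-class death counts for a mortality profile
#'
#' Fractional counts are allowed: a mandible split between adjacent wear
#' classes contributes its weight to each.
#'
#' @param counts Non-negative numeric vector, one entry per age class.
#' @param labels Class labels; default Payne A--I when the length matches,
#'   otherwise `class1..classK`.
#' @return Object of class `mortality_counts`.
#' @export
mortality_counts <- function(counts, labels = NULL) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (length(counts) == 9L) payne_classes()$class
              else paste0("class", seq_along(counts))
  }
  if (anyDuplicated(labels)) stop("class labels must be unique", call. = FALSE)
  structure(list(labels = as.character(labels), counts = counts,
                 n_total = sum(counts)),
            class = "mortality_counts")
}

#' @export
print.mortality_counts <- function(x, ...) {
  cat(sprintf("Mortality counts (n = %g):\n", x$n_total))
  print(stats::setNames(x$counts, x$labels))
  invisible(x)
}

#' Mortality profile with Dirichlet credibility intervals
#'
#' Places a Dirichlet posterior on the class proportions,
#' `Dirichlet(counts + prior)`, and derives equal-tailed credibility
#' intervals from seeded Monte-Carlo draws. The analytic Beta marginals of
#' the Dirichlet are also returned as an independent cross-check of the
#' Monte-Carlo interval endpoints. Survivorship `S(k) = 1 - sum_{j<=k} p_j`
#' is computed per draw, so its intervals respect monotonicity.
#'
#' @param counts A [mortality_counts()] object or bare numeric vector.
#' @param level Credibility level, default 0.95.
#' @param prior Per-class pseudo-counts: a scalar (recycled) or vector.
#'   Default flat `Dirichlet(1, ..., 1)`; use 0.5 for Jeffreys.
#' @param n_draws Monte-Carlo draws, default 10000.
#' @param seed Mandatory seed for the draws.
#' @return Object of class `mortality_profile`: data frame `classes` with
#'   per-class point estimates (posterior means), Monte-Carlo and analytic
#'   Beta interval endpoints, and survivorship estimates with intervals;
#'   plus `level`, `n_draws`, `seed`.
#' @examples
#' p <- dirichlet_profile(mortality_counts(c(2, 3, 5)), seed = 1)
#' p$classes$prop
#' @export
dirichlet_profile <- function(counts, level = 0.95, prior = 1,
                              n_draws = 10000L, seed) {
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  if (!inherits(counts, "mortality_counts")) counts <- mortality_counts(counts)
  k <- length(counts$counts)
  prior <- rep_len(prior, k)
  alpha <- counts$counts + prior
  if (all(alpha == 0)) stop("all-zero counts with zero prior", call. = FALSE)
  a0 <- sum(alpha)
  lo <- (1 - level) / 2; hi <- 1 - lo

  draws <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_draws * k, shape = rep(alpha, each = n_draws)),
                nrow = n_draws, ncol = k)
    g / rowSums(g)
  })
  surv <- 1 - t(apply(draws, 1L, cumsum))  # n_draws x k, per-draw survivorship

  classes <- data.frame(
    class = counts$labels,
    count = counts$counts,
    prop = alpha / a0,                       # posterior mean
    lower = apply(draws, 2L, stats::quantile, lo),
    upper = apply(draws, 2L, stats::quantile, hi),
    beta_lower = stats::qbeta(lo, alpha, a0 - alpha),
    beta_upper = stats::qbeta(hi, alpha, a0 - alpha),
    surv = colMeans(surv),
    surv_lower = apply(surv, 2L, stats::quantile, lo),
    surv_upper = apply(surv, 2L, stats::quantile, hi),
    stringsAsFactors = FALSE
  )
  rownames(classes) <- NULL
  structure(list(classes = classes, level = level, n_draws = n_draws,
                 seed = seed, prior = prior),
            class = "mortality_profile")
}

#' @export
print.mortality_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Dirichlet mortality profile (%d%% credibility, %d draws, seed %s)\n",
              round(100 * x$level), x$n_draws, x$seed))
  df <- x$classes[, c("class", "count", "prop", "lower", "upper", "surv")]
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mortality_profile <- function(x, ...) {
  cl <- x$classes
  bp <- graphics::barplot(cl$prop, names.arg = cl$class,
                          ylim = c(0, max(cl$upper) * 1.05),
                          ylab = "proportion of deaths", ...)
  graphics::arrows(bp, cl$lower, bp, cl$upper, angle = 90, code = 3,
                   length = 0.04)
  invisible(x)
}

#' Taphonomic flag proportions with Wilson intervals
#'
#' Proportion of the assemblage (NISP) affected by each taphonomic flag,
#' with Wilson 95% score intervals.
#'
#' @param flagged Named numeric vector (or single number) of flagged
#'   specimen counts.
#' @param nisp Total number of identified specimens.
#' @param level Confidence level, default 0.95.
#' @return Data frame `flag`, `count`, `nisp`, `proportion_pct`,
#'   `lower_pct`, `upper_pct`.
#' @examples
#' taphonomy_proportions(c(butchery = 70, burning = 21), nisp = 410)
#' @export
taphonomy_proportions <- function(flagged, nisp, level = 0.95) {
  if (nisp < 1) stop("nisp must be >= 1", call. = FALSE)
  if (any(flagged < 0) || any(flagged > nisp)) {
    stop("flagged counts must lie in [0, nisp]", call. = FALSE)
  }
  if (is.null(names(flagged))) names(flagged) <- paste0("flag", seq_along(flagged))
  ci <- t(vapply(flagged, function(k) {
    # Wilson score interval (prop.test without continuity correction)
    stats::prop.test(k, nisp, correct = FALSE, conf.level = level)$conf.int
  }, numeric(2)))
  data.frame(flag = names(flagged), count = as.numeric(flagged), nisp = nisp,
             proportion_pct = 100 * as.numeric(flagged) / nisp,
             lower_pct = 100 * ci[, 1], upper_pct = 100 * ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marean completeness index
#'
#' Mean of per-specimen completeness fractions, expressed as a percentage.
#' Conventionally computed on compact tarsals (astragali), which survive
#' attrition well.
#'
#' @param fractions Per-specimen completeness fractions in \[0, 1\].
#' @return Completeness percentage.
#' @export
completeness_index <- function(fractions) {
  fractions <- fractions[!is.na(fractions)]
  if (!length(fractions)) stop("no completeness records", call. = FALSE)
  if (any(fractions < 0 | fractions > 1)) {
    stop("completeness fractions must lie in [0, 1]", call. = FALSE)
  }
  100 * mean(fractions)
}

#' MAU% (minimal animal units, percent of maximum)
#'
#' `MAU = count / expected-per-skeleton`, scaled to the most abundant
#' element: `MAU% = 100 * MAU / max(MAU)`.
#'
#' @param counts Named numeric vector of element counts.
#' @param expected Expected number of each element per complete skeleton
#'   (recycled if scalar).
#' @return Data frame `element`, `count`, `expected`, `mau`, `mau_pct`.
#' @export
mau_percent <- function(counts, expected) {
  expected <- rep_len(expected, length(counts))
  if (any(expected <= 0)) stop("expected counts must be > 0", call. = FALSE)
  if (all(counts == 0)) stop("all element counts are zero", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- paste0("element", seq_along(counts))
  mau <- counts / expected
  data.frame(element = names(counts), count = as.numeric(counts),
             expected = expected, mau = as.numeric(mau),
             mau_pct = 100 * as.numeric(mau) / max(mau),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test for density-mediated attrition
#'
#' Correlates element MAU% against a bone mineral density reference keyed by
#' element/scan site. A positive, significant correlation (denser elements
#' preserved better) is read as an attrition signal; both rank and linear
#' correlations are computed since either convention is found in the
#' literature.
#'
#' @param mau Data frame from [mau_percent()] (or with columns `element`,
#'   `mau_pct`).
#' @param density Data frame with columns `element` and `density`.
#' @param alpha Significance level for the verdict, default 0.05.
#' @return List `spearman_rho`, `spearman_p`, `pearson_r`, `pearson_p`,
#'   `n`, `verdict` (`"attrition signal"` or `"no attrition signal"`).
#' @export
density_attrition_test <- function(mau, density, alpha = 0.05) {
  m <- merge(mau[, c("element", "mau_pct")], density[, c("element", "density")],
             by = "element")
  miss <- setdiff(mau$element, density$element)
  if (length(miss)) {
    stop(sprintf("no density reference for: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(m) < 5L) stop("need >= 5 matched element/scan-site pairs", call. = FALSE)
  constant <- stats::sd(m$mau_pct) == 0 || stats::sd(m$density) == 0
  if (constant) {
    sp_rho <- sp_p <- pe_r <- pe_p <- NA_real_
  } else {
    sp <- suppressWarnings(stats::cor.test(m$mau_pct, m$density, method = "spearman"))
    pe <- stats::cor.test(m$mau_pct, m$density, method = "pearson")
    sp_rho <- unname(sp$estimate); sp_p <- sp$p.value
    pe_r <- unname(pe$estimate); pe_p <- pe$p.value
  }
  signal <- !constant && is.finite(sp_rho) && sp_rho > 0 && sp_p < alpha
  list(spearman_rho = sp_rho, spearman_p = sp_p,
       pearson_r = pe_r, pearson_p = pe_p, n = nrow(m),
       verdict = if (signal) "attrition signal" else "no attrition signal")
}
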