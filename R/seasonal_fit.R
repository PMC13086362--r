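# Cosine seasonality model for intra-tooth d18O sequences.
#
# Base model: d18O(x) = A * cos(2*pi*(x - x0)/X) + M
# with A the amplitude ((max - min)/2, permil), X the period (mm of crown
# per annual cycle), x0 the position of the d18O maximum (mm from ERJ) and
# M the mean ((max + min)/2, permil). Opt-in extensions: exponential
# damping A * exp((x - X_B)/X_A) of the amplitude towards the ERJ, a linear
# trend p*x, and a linear phase drift b*x inside the cosine.
#
# For fixed X the base model is linear in (A*cos(phi), A*sin(phi), M)
# because A*cos(2*pi*(x - x0)/X) = a*cos(2*pi*x/X) + b*sin(2*pi*x/X) with
# a = A*cos(2*pi*x0/X), b = A*sin(2*pi*x0/X). The fit therefore profiles the
# period on a grid plus 1-D refinement, which sidesteps the notorious
# multimodality of sinusoid fitting in phase; a trust-region nonlinear
# polish then refines all parameters jointly.

# linear profile fit at fixed period X; optionally with linear drift term
profile_cosine_at <- function(x, y, X, drift = FALSE) {
  C <- cos(2 * pi * x / X); S <- sin(2 * pi * x / X)
  mm <- if (drift) cbind(1, C, S, x) else cbind(1, C, S)
  cf <- tryCatch(stats::lm.fit(mm, y)$coefficients, error = function(e) NULL)
  if (is.null(cf) || anyNA(cf)) return(list(sse = Inf))
  fit <- drop(mm %*% cf)
  cf <- unname(cf)
  a <- cf[2]; b <- cf[3]
  list(sse = sum((y - fit)^2), M = cf[1], a = a, b = b,
       p = if (drift) cf[4] else 0,
       A = sqrt(a^2 + b^2),
       x0 = (atan2(b, a) / (2 * pi) * X) %mod% X)
}

# grid + golden-section profile over the period
profile_cosine <- function(x, y, drift = FALSE,
                           X_range = NULL, n_grid = 80L) {
  span <- diff(range(x))
  if (is.null(X_range)) X_range <- c(0.5, 2) * span
  grid <- seq(X_range[1], X_range[2], length.out = n_grid)
  sses <- vapply(grid, function(X) profile_cosine_at(x, y, X, drift)$sse, 0)
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(X) profile_cosine_at(x, y, X, drift)$sse,
                         interval = c(lo, hi))
  best <- profile_cosine_at(x, y, opt$minimum, drift)
  best$X <- opt$minimum
  best
}

#' Fit the cosine seasonality model to a tooth d18O sequence
#'
#' Estimates amplitude `A`, period `X` (mm of crown per annual cycle),
#' position of the d18O maximum `x0` and mean `M` by least squares. The
#' period is profiled on a grid (the model is linear in the remaining
#' parameters at fixed period) and all parameters are then polished with
#' trust-region nonlinear least squares. `x0` is folded so that
#' `x0_over_X = (x0 mod X)/X` lies in `[0, 1)`; the fitted curve attains its
#' maximum at `x = x0`.
#'
#' @param seq A [tooth_sequence()], or a data frame with `distance_mm` and
#'   `d18O` columns.
#' @param model `"basic"` (plain cosine), `"drift"` (adds a linear trend
#'   `p*x`), or `"damped"` (adds exponential amplitude damping
#'   `exp((x - X_B)/X_A)` with `X_B` fixed at the occlusal end).
#' @param force Fit even if [screen_sequence()] marks the sequence
#'   ineligible.
#' @param rules Screening thresholds, see [screening_rules()].
#' @param X_range Period search bounds in mm; default `c(0.5, 2)` times the
#'   sampled span.
#' @return An object of class `seasonal_fit` with components `A`, `X`, `x0`,
#'   `M`, `x0_over_X`, `drift_slope`, `damping` (`X_A`, `X_B` or `NULL`),
#'   `rmse`, `n_used`, `converged`, `screen`, plus data and call; methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' x <- seq(0, 30, 1)
#' ts <- tooth_sequence("demo", x, 3 * cos(2 * pi * (x - 10) / 25) - 5)
#' fit <- fit_seasonal_cosine(ts)
#' coef(fit)
#' @export
fit_seasonal_cosine <- function(seq, model = c("basic", "drift", "damped"),
                                force = FALSE, rules = screening_rules(),
                                X_range = NULL) {
  model <- match.arg(model)
  if (inherits(seq, "tooth_sequence")) {
    scr <- screen_sequence(seq, rules)
    if (!scr$eligible && !force) {
      stop(sprintf("sequence fails screening (%s); use force = TRUE to override",
                   paste(scr$reasons, collapse = ", ")), call. = FALSE)
    }
    id <- attr(seq, "specimen_id")
  } else {
    scr <- list(eligible = NA, reasons = character(0))
    id <- "unknown"
  }
  x <- seq$distance_mm; y <- seq$d18O
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("at least 4 samples required to fit", call. = FALSE)
  span <- diff(range(x))
  if (is.null(X_range)) X_range <- c(0.5, 2) * span
  if (X_range[1] <= 0 || X_range[2] <= X_range[1]) {
    stop("invalid period bounds", call. = FALSE)
  }

  prof <- profile_cosine(x, y, drift = (model == "drift"), X_range = X_range)
  A <- prof$A; X <- prof$X; x0 <- prof$x0; M <- prof$M; p <- prof$p
  converged <- TRUE
  X_A <- NULL; X_B <- NULL

  if (model == "damped") {
    X_B <- max(x)  # anchor so exp() = 1 at the occlusal end of the series
    fml <- y ~ A * exp((x - X_B) / X_A) * cos(2 * pi * (x - x0) / X) + M
    start <- list(A = max(A, 1e-3), X_A = 10 * span, x0 = x0, X = X, M = M)
    nl <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y, X_B = X_B),
                        start = start,
                        lower = c(A = 1e-6, X_A = 0.5, x0 = -2 * X,
                                  X = X_range[1], M = -Inf),
                        upper = c(A = 2 * diff(range(y)), X_A = Inf,
                                  x0 = 2 * X, X = X_range[2], M = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      A <- unname(cf["A"]); X_A <- unname(cf["X_A"]); x0 <- unname(cf["x0"])
      X <- unname(cf["X"]); M <- unname(cf["M"])
      converged <- isTRUE(nl$convInfo$isConv)
    } else converged <- FALSE
  } else {
    # polish the profiled solution jointly (A, X, x0, M [, p])
    fml <- if (model == "drift") {
      y ~ A * cos(2 * pi * (x - x0) / X) + M + p * x
    } else y ~ A * cos(2 * pi * (x - x0) / X) + M
    start <- list(A = max(A, 1e-3), x0 = x0, X = X, M = M)
    lower <- c(A = 1e-6, x0 = -2 * X, X = X_range[1], M = -Inf)
    upper <- c(A = 2 * max(diff(range(y)), 1e-3), x0 = 2 * X, X = X_range[2], M = Inf)
    if (model == "drift") {
      start$p <- p; lower <- c(lower, p = -Inf); upper <- c(upper, p = Inf)
    }
    nl <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf <- stats::coef(nl)
      sse_nl <- sum(stats::resid(nl)^2)
      if (sse_nl <= prof$sse + 1e-12) {
        A <- unname(cf["A"]); x0 <- unname(cf["x0"]); X <- unname(cf["X"])
        M <- unname(cf["M"]); if (model == "drift") p <- unname(cf["p"])
        converged <- isTRUE(nl$convInfo$isConv)
      }
    }
  }

  if (A < 0) { A <- -A; x0 <- x0 + X / 2 }  # canonical A > 0
  x0 <- x0 %mod% X
  fitted_vals <- predict_cosine(x, A, X, x0, M, p, X_A, X_B)
  res <- y - fitted_vals
  out <- structure(list(
    specimen_id = id, model = model,
    A = A, X = X, x0 = x0, M = M,
    x0_over_X = (x0 %mod% X) / X,
    drift_slope = if (model == "drift") p else NULL,
    damping = if (model == "damped") list(X_A = X_A, X_B = X_B) else NULL,
    rmse = sqrt(mean(res^2)), n_used = length(x), converged = converged,
    screen = scr,
    data = data.frame(distance_mm = x, d18O = y),
    fitted = fitted_vals, residuals = res,
    call = match.call()
  ), class = "seasonal_fit")
  out
}

predict_cosine <- function(x, A, X, x0, M, p = 0, X_A = NULL, X_B = NULL) {
  amp <- if (!is.null(X_A)) A * exp((x - X_B) / X_A) else A
  amp * cos(2 * pi * (x - x0) / X) + M + p * x
}

#' @export
coef.seasonal_fit <- function(object, ...) {
  out <- c(A = object$A, X = object$X, x0 = object$x0, M = object$M,
           x0_over_X = object$x0_over_X)
  if (!is.null(object$drift_slope)) out <- c(out, p = object$drift_slope)
  if (!is.null(object$damping)) {
    out <- c(out, X_A = object$damping$X_A, X_B = object$damping$X_B)
  }
  out
}

#' @export
print.seasonal_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cosine seasonality fit (%s model): specimen %s\n",
              x$model, x$specimen_id))
  print(round(coef(x), digits))
  cat(sprintf("rmse %.3f permil on %d samples; converged: %s\n",
              x$rmse, x$n_used, x$converged))
  invisible(x)
}

#' @export
summary.seasonal_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.seasonal_fit")
}

#' @export
print.summary.seasonal_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("d18O maximum at %.2f mm from ERJ; x0/X = %.3f (angle %.1f deg)\n",
              f$x0, f$x0_over_X, f$x0_over_X * 360))
  if (!is.na(f$screen$eligible))
    cat(sprintf("screening: %s%s\n",
                if (isTRUE(f$screen$eligible)) "eligible" else "ineligible",
                if (length(f$screen$reasons))
                  paste0(" (", paste(f$screen$reasons, collapse = ", "), ")") else ""))
  invisible(x)
}

#' @export
predict.seasonal_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance_mm else {
    if (is.data.frame(newdata)) newdata$distance_mm else as.numeric(newdata)
  }
  predict_cosine(x, object$A, object$X, object$x0, object$M,
                 p = if (is.null(object$drift_slope)) 0 else object$drift_slope,
                 X_A = object$damping$X_A, X_B = object$damping$X_B)
}

#' @export
fitted.seasonal_fit <- function(object, ...) object$fitted

#' @export
residuals.seasonal_fit <- function(object, ...) object$residuals

#' @export
plot.seasonal_fit <- function(x, ...) {
  d <- x$data
  xs <- seq(min(d$distance_mm), max(d$distance_mm), length.out = 200)
  graphics::plot(d$distance_mm, d$d18O, xlab = "distance from ERJ (mm)",
                 ylab = expression(delta^18 * O ~ "(permil VPDB)"),
                 main = sprintf("Specimen %s", x$specimen_id), ...)
  graphics::lines(xs, predict(x, xs), col = "steelblue", lwd = 2)
  graphics::abline(v = x$x0 %mod% x$X, lty = 2, col = "grey40")
  invisible(x)
}
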