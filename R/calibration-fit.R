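#' Fit a calibration curve by orthogonal distance regression
#'
#' Fits the dependence of the photoswitching ratio on the FRET metric from
#' pooled per-cell calibration measurements.  Both coordinates of a
#' calibration point are measured quantities, so the fit minimises orthogonal
#' (errors-in-both-variables) residuals rather than vertical ones, assuming
#' equal error scales on both axes.
#'
#' For `kind = "linear"` the orthogonal fit has a closed form (the principal
#' axis of the centred point cloud, i.e. Deming regression with unit variance
#' ratio).  For the nonlinear kinds the sum of squared point-to-curve
#' distances is minimised, with the foot point of each datum found by an
#' inner one-dimensional minimisation.  The double-exponential fit uses five
#' deterministic starts derived from a single-exponential log-linear fit and
#' keeps the best optimum.
#'
#' @param thetas Abscissa values (FRET efficiency in `[0, 1]`, or emission
#'   ratio when `abscissa = "ratio"`).
#' @param rhos Measured photoswitching ratios.
#' @param kind `"linear"`, `"power_law"` or `"double_exponential"`.
#' @param channel,abscissa Recorded in the returned model; see
#'   [calibration_model()].
#' @return A [calibration_model()] with the fitted coefficients, the convex
#'   hull of `thetas` as `valid_range`, and the orthogonal residual norm.
#' @examples
#' th <- seq(0, 0.6, length.out = 20)
#' fit_calibration(th, 0.6 - 0.2 * th, kind = "linear")
#' @export
fit_calibration <- function(thetas, rhos,
                            kind = c("linear", "power_law", "double_exponential"),
                            channel = c("donor", "acceptor"),
                            abscissa = c("theta", "ratio")) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  abscissa <- match.arg(abscissa)
  thetas <- as.numeric(thetas); rhos <- as.numeric(rhos)
  if (length(thetas) != length(rhos) || any(!is.finite(thetas)) ||
      any(!is.finite(rhos))) {
    stop_pcfret("thetas and rhos must be equal-length finite vectors",
                "pcfret_invalid_input")
  }
  if (abscissa == "theta" && any(thetas < 0 | thetas > 1)) {
    stop_pcfret("thetas must lie in [0, 1]", "pcfret_invalid_input")
  }
  n_min <- switch(kind, linear = 2L, power_law = 2L, double_exponential = 5L)
  if (length(unique(thetas)) < n_min) {
    stop_pcfret(sprintf("'%s' fit needs at least %d distinct points", kind, n_min),
                "pcfret_invalid_input")
  }

  fit <- switch(kind,
    linear = .odr_linear(thetas, rhos),
    power_law = .odr_power_law(thetas, rhos),
    double_exponential = .odr_double_exp(thetas, rhos))
  if (any(!is.finite(fit$params))) {
    stop_pcfret("calibration fit did not converge to finite parameters",
                "pcfret_fit_failure")
  }
  calibration_model(kind = kind, params = fit$params, channel = channel,
                    valid_range = range(thetas), abscissa = abscissa,
                    residual_norm = sqrt(fit$ss))
}

# ---- orthogonal-distance machinery ----------------------------------------

# Closed-form total least squares: the orthogonal regression line is the
# first principal axis of the centred data.
.odr_linear <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2); syy <- sum((y - yb)^2); sxy <- sum((x - xb) * (y - yb))
  if (abs(sxy) < .Machine$double.eps * max(sxx, syy, 1)) {
    m <- 0
  } else {
    m <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  q <- yb - m * xb
  # orthogonal residual sum of squares
  ss <- sum((y - m * x - q)^2) / (1 + m^2)
  list(params = c(m = m, q = q), ss = ss)
}

# Squared orthogonal distance from (x0, y0) to the curve y = fun(x),
# minimised over the foot point x in [lo, hi].
.odr_point_ss <- function(fun, x0, y0, lo, hi) {
  optimize(function(x) (x - x0)^2 + (fun(x) - y0)^2,
           lower = lo, upper = hi, tol = 1e-12)$objective
}

.odr_ss <- function(fun, x, y, lo, hi) {
  sum(vapply(seq_along(x),
             function(i) .odr_point_ss(fun, x[i], y[i], lo, hi), numeric(1)))
}

.odr_power_law <- function(x, y) {
  span <- diff(range(x))
  lo <- min(x) - 0.5 * span - 0.1; hi <- max(x) + 0.5 * span + 0.1
  obj <- function(r0) .odr_ss(function(t) r0^(1 - t), x, y, lo, hi)
  opt <- optimize(obj, lower = 1e-8, upper = 1, tol = 1e-10)
  # polish around the optimum: golden search stops early on flat objectives
  opt2 <- optimize(obj, lower = max(1e-8, opt$minimum - 1e-4),
                   upper = min(1, opt$minimum + 1e-4), tol = 1e-12)
  best <- if (opt2$objective <= opt$objective) opt2 else opt
  list(params = c(rho0 = best$minimum), ss = best$objective)
}

.odr_double_exp <- function(x, y) {
  span <- diff(range(x))
  lo <- min(x) - 0.5 * span - 0.1; hi <- max(x) + 0.5 * span + 0.1
  # objective over log-amplitudes to keep a1, a2 >= 0
  obj <- function(p) {
    a1 <- exp(p[1]); k1 <- p[2]; a2 <- exp(p[3]); k2 <- p[4]
    .odr_ss(function(t) a1 * exp(-k1 * t) + a2 * exp(-k2 * t), x, y, lo, hi)
  }
  # heuristic single-exponential start from a log-linear fit
  ypos <- pmax(y, 1e-8)
  lf <- lm(log(ypos) ~ x)
  a0 <- exp(coef(lf)[[1]]); k0 <- -coef(lf)[[2]]
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(y), 1e-3)
  if (!is.finite(k0)) k0 <- 0
  starts <- list(
    c(log(0.7 * a0), k0, log(0.3 * a0), 3 * k0 + 0.5),
    c(log(0.5 * a0), 0.5 * k0, log(0.5 * a0), 2 * k0 + 1),
    c(log(0.9 * a0), k0, log(0.1 * a0), 5 * k0 + 2),
    c(log(0.5 * a0), k0 - 1, log(0.5 * a0), k0 + 1),
    c(log(0.3 * a0), -abs(k0) - 0.5, log(0.7 * a0), abs(k0) + 0.5))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop_pcfret("double-exponential calibration fit failed from all starts",
                "pcfret_fit_failure")
  }
  p <- best$par
  list(params = c(a1 = exp(p[1]), k1 = p[2], a2 = exp(p[3]), k2 = p[4]),
       ss = best$value)
}
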