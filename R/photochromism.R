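#' Photoswitching ratios from paired on/off acquisitions
#'
#' The photoswitching ratio is the fraction of fluorescence remaining after
#' the off-switching light dose.  In the donor channel
#' `rho_d = s_dd_off / s_dd_on`.  In the acceptor channel two definitions are
#' supported: the corrected form `rho_a = F_c_off / F_c_on` when correction
#' factors are available, otherwise the raw form `rho_a = s_da_off / s_da_on`.
#' Either is valid provided it is used consistently with the calibration.
#'
#' Energy transfer competes with photochromism, so both ratios depend on the
#' FRET efficiency; see [rho_from_theta_power()] and [fit_calibration()].
#'
#' Ratios slightly above 1 occur under noise and are tolerated up to 1.05;
#' larger values are still returned but flagged with a warning of class
#' `"pcfret_rho_above_one"`.
#'
#' @param on,off [fret_acquisition()] objects in the `"on"` and `"off"`
#'   switching states.
#' @param cf Optional [correction_factors()]; when supplied, `rho_a` is
#'   computed on the sensitized emission (mode `"corrected"`).
#' @return A list of class `"photoswitching_ratios"` with elements `rho_d`,
#'   `rho_a` and `rho_a_mode`.
#' @examples
#' on  <- fret_acquisition(s_dd = 1000, s_da = 400, state = "on")
#' off <- fret_acquisition(s_dd = 300, s_da = 100, state = "off")
#' photoswitching_ratios(on, off)
#' @export
photoswitching_ratios <- function(on, off, cf = NULL) {
  stopifnot(inherits(on, "fret_acquisition"), inherits(off, "fret_acquisition"))
  if (on$state != "on" || off$state != "off") {
    stop_pcfret("'on' must be an on-state and 'off' an off-state acquisition",
                "pcfret_invalid_input")
  }
  if (on$s_dd <= 0) {
    stop_pcfret("on-state s_dd must be > 0", "pcfret_degenerate")
  }
  rho_d <- off$s_dd / on$s_dd
  if (!is.null(cf)) {
    stopifnot(inherits(cf, "correction_factors"))
    fc_on <- sensitized_emission(on, cf)
    fc_off <- sensitized_emission(off, cf)
    if (fc_on <= 0) {
      stop_pcfret("on-state sensitized emission must be > 0 for corrected rho_a",
                  "pcfret_degenerate")
    }
    rho_a <- fc_off / fc_on
    mode <- "corrected"
  } else {
    if (on$s_da <= 0) {
      stop_pcfret("on-state s_da must be > 0 for raw rho_a", "pcfret_degenerate")
    }
    rho_a <- off$s_da / on$s_da
    mode <- "raw"
  }
  if (rho_d > 1.05 || rho_a > 1.05) {
    warning(warningCondition(
      sprintf("photoswitching ratio above 1.05 (rho_d=%.3f, rho_a=%.3f)",
              rho_d, rho_a),
      class = "pcfret_rho_above_one"))
  }
  structure(list(rho_d = rho_d, rho_a = rho_a, rho_a_mode = mode),
            class = "photoswitching_ratios")
}

#' Photoswitching ratio as a function of FRET efficiency (quantum-yield model)
#'
#' For a single FRET species with an intrinsic off-switching quantum yield,
#' energy transfer competes with photochromism and the photoswitching ratio
#' follows `rho = rho0^(1 - theta)`, where `rho0` is the ratio measured in
#' the absence of FRET under identical illumination.  In this regime the
#' donor- and acceptor-channel ratios coincide, because the acceptor emission
#' is proportional to the amount of donor in the fluorescent state.
#'
#' Limits: `rho(0) = rho0`, `rho(1) = 1` (complete transfer suppresses
#' switching); strictly increasing in `theta` for `rho0 < 1`.
#'
#' @param theta FRET efficiencies in `[0, 1]` (vectorised).
#' @param rho0 No-FRET photoswitching ratio in `(0, 1]`.
#' @return Photoswitching ratios.
#' @examples
#' rho_from_theta_power(c(0, 0.5, 1), rho0 = 0.25)
#' @export
rho_from_theta_power <- function(theta, rho0) {
  .assert_scalar_num(rho0, "rho0")
  if (rho0 <= 0 || rho0 > 1) {
    stop_pcfret("rho0 must lie in (0, 1]", "pcfret_invalid_input")
  }
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 1)) {
    stop_pcfret("theta must lie in [0, 1]", "pcfret_invalid_input")
  }
  rho0^(1 - theta)
}

#' Construct a calibration model
#'
#' A calibration model maps the FRET metric of a pair (efficiency `theta`, or
#' a (sensitized) emission ratio) to its photoswitching ratio in one channel.
#' Three functional forms are supported:
#'
#' * `"power_law"`: `rho0^(1 - theta)` — the single-species quantum-yield
#'   model; `params = c(rho0 = ...)`.
#' * `"double_exponential"`: `a1 * exp(-k1 * theta) + a2 * exp(-k2 * theta)` —
#'   empirical form for biosensors with interconverting states;
#'   `params = c(a1, k1, a2, k2)`.
#' * `"linear"`: `m * theta + q` — empirical form for nearly photostatic
#'   donors; `params = c(m = ..., q = ...)`.
#'
#' @param kind One of `"power_law"`, `"double_exponential"`, `"linear"`.
#' @param params Named numeric vector of coefficients (see above).
#' @param channel `"donor"` or `"acceptor"`.
#' @param valid_range Range of the abscissa covered by the calibration data.
#' @param abscissa The metric the model is expressed against: `"theta"`
#'   (FRET efficiency) or `"ratio"` (sensitized emission ratio).  The
#'   unmixing solver iterates on the same metric.
#' @param residual_norm Optional goodness-of-fit (orthogonal residual norm).
#' @return An object of class `"calibration_model"`.
#' @export
calibration_model <- function(kind = c("power_law", "double_exponential", "linear"),
                              params, channel = c("donor", "acceptor"),
                              valid_range = c(0, 1),
                              abscissa = c("theta", "ratio"),
                              residual_norm = NA_real_) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  abscissa <- match.arg(abscissa)
  params <- unlist(params)
  need <- switch(kind,
    power_law = "rho0",
    double_exponential = c("a1", "k1", "a2", "k2"),
    linear = c("m", "q"))
  if (is.null(names(params)) || !all(need %in% names(params))) {
    # accept positional parameters in the documented order
    if (length(params) == length(need)) {
      names(params) <- need
    } else {
      stop_pcfret(sprintf("'%s' model needs parameters: %s", kind,
                          paste(need, collapse = ", ")),
                  "pcfret_invalid_input")
    }
  }
  params <- params[need]
  if (any(!is.finite(params))) {
    stop_pcfret("calibration parameters must be finite", "pcfret_invalid_input")
  }
  if (kind == "power_law" && (params[["rho0"]] <= 0 || params[["rho0"]] > 1)) {
    stop_pcfret("power_law requires rho0 in (0, 1]", "pcfret_invalid_input")
  }
  stopifnot(length(valid_range) == 2L, valid_range[1] <= valid_range[2])
  structure(list(kind = kind, params = params, channel = channel,
                 valid_range = as.numeric(valid_range), abscissa = abscissa,
                 residual_norm = as.numeric(residual_norm)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s (%s channel, vs %s)\n",
              x$kind, x$channel, x$abscissa))
  cat("  params:", paste(sprintf("%s=%.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  valid range: [%g, %g]", x$valid_range[1], x$valid_range[2]))
  if (is.finite(x$residual_norm)) cat(sprintf("  resid: %.3g", x$residual_norm))
  cat("\n")
  invisible(x)
}

# Raw functional forms, no range handling.
.cal_fun <- function(model) {
  p <- model$params
  switch(model$kind,
    power_law = function(x) p[["rho0"]]^(1 - x),
    double_exponential = function(x) {
      p[["a1"]] * exp(-p[["k1"]] * x) + p[["a2"]] * exp(-p[["k2"]] * x)
    },
    linear = function(x) p[["m"]] * x + p[["q"]])
}

#' Evaluate a calibration model
#'
#' Returns the photoswitching ratio predicted at the given abscissa values.
#' Values outside the model's `valid_range` are evaluated at the nearest
#' endpoint (the empirical fits are not trusted to extrapolate); the result
#' carries a logical `"clamped"` attribute marking those entries.
#'
#' @param model A [calibration_model()].
#' @param theta Abscissa values (FRET efficiency or ratio, matching
#'   `model$abscissa`).
#' @return Predicted photoswitching ratios with attribute `"clamped"`.
#' @export
evaluate_calibration <- function(model, theta) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(theta))) {
    stop_pcfret("theta must be finite", "pcfret_invalid_input")
  }
  lo <- model$valid_range[1]; hi <- model$valid_range[2]
  clamped <- theta < lo | theta > hi
  x <- pmin(pmax(theta, lo), hi)
  out <- .cal_fun(model)(x)
  attr(out, "clamped") <- clamped
  out
}
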