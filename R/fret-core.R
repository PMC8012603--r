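#' Construct a FRET acquisition
#'
#' A single-timepoint sensitized-emission FRET acquisition consists of up to
#' three intensity measurements: the donor-excited donor emission `s_dd`, the
#' donor-excited acceptor emission `s_da`, and the directly excited acceptor
#' emission `s_aa`.  For a photochromic donor, each acquisition is taken in a
#' defined switching state (`"on"` after on-switching light, `"off"` after the
#' off-switching dose).
#'
#' `s_aa` varies slowly (it is affected only by photodestruction or large
#' structural changes) and is typically measured at a reduced frequency; it
#' may therefore be absent (`NA`).  See [fill_saa()] for interpolation across
#' a time series.
#'
#' @param s_dd,s_da Nonnegative intensities (photons or background-corrected
#'   camera counts).
#' @param s_aa Nonnegative intensity, or `NA` when not measured at this
#'   timepoint.
#' @param state `"on"` or `"off"` switching state.
#' @param time Acquisition time in seconds (optional).
#' @return An object of class `"fret_acquisition"`.
#' @examples
#' fret_acquisition(s_dd = 500, s_da = 120, s_aa = 200, state = "on")
#' @export
fret_acquisition <- function(s_dd, s_da, s_aa = NA_real_,
                             state = c("on", "off"), time = NA_real_) {
  state <- match.arg(state)
  .assert_scalar_num(s_dd, "s_dd")
  .assert_scalar_num(s_da, "s_da")
  .assert_scalar_num(s_aa, "s_aa", allow_na = TRUE)
  .assert_scalar_num(time, "time", allow_na = TRUE)
  if (s_dd < 0 || s_da < 0 || (!is.na(s_aa) && s_aa < 0)) {
    stop_pcfret("intensities must be nonnegative", "pcfret_invalid_input")
  }
  structure(list(s_dd = as.numeric(s_dd), s_da = as.numeric(s_da),
                 s_aa = as.numeric(s_aa), state = state,
                 time = as.numeric(time)),
            class = "fret_acquisition")
}

#' @export
print.fret_acquisition <- function(x, ...) {
  cat(sprintf("<fret_acquisition [%s]> s_dd=%g s_da=%g s_aa=%s\n",
              x$state, x$s_dd, x$s_da,
              if (is.na(x$s_aa)) "NA" else format(x$s_aa)))
  invisible(x)
}

#' Cross-talk and brightness correction factors
#'
#' `alpha` is the donor bleed-through into the acceptor detection channel,
#' `delta` the direct acceptor cross-excitation under donor excitation, and
#' `gamma` the brightness/collection factor linking the corrected sensitized
#' emission to an absolute FRET efficiency.  All three are instrument- and
#' fluorophore-specific.  `gamma` cannot be measured from the acquisitions
#' themselves and must be supplied by the user (from control experiments or
#' spectra); it defaults to 1, in which case [fret_efficiency()] returns an
#' apparent efficiency.
#'
#' @param alpha,delta Dimensionless, finite and `>= 0`.
#' @param gamma Dimensionless, finite and `> 0`.
#' @return An object of class `"correction_factors"`.
#' @examples
#' correction_factors(alpha = 0.1, delta = 0.05, gamma = 1)
#' @export
correction_factors <- function(alpha = 0, delta = 0, gamma = 1) {
  .assert_scalar_num(alpha, "alpha")
  .assert_scalar_num(delta, "delta")
  .assert_scalar_num(gamma, "gamma")
  if (alpha < 0 || delta < 0) {
    stop_pcfret("'alpha' and 'delta' must be >= 0", "pcfret_invalid_input")
  }
  if (gamma <= 0) {
    stop_pcfret("'gamma' must be > 0", "pcfret_invalid_input")
  }
  structure(list(alpha = as.numeric(alpha), delta = as.numeric(delta),
                 gamma = as.numeric(gamma)),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("<correction_factors> alpha=%g delta=%g gamma=%g\n",
              x$alpha, x$delta, x$gamma))
  invisible(x)
}

#' Estimate cross-talk factors from single-fluorophore controls
#'
#' Donor bleed-through `alpha` is the ratio `s_da / s_dd` measured on a
#' donor-only sample; acceptor cross-excitation `delta` is `s_da / s_aa`
#' measured on an acceptor-only sample.  The brightness factor `gamma` is not
#' estimable from these controls and passes through unchanged.
#'
#' @param donor_only A [fret_acquisition()] of a sample containing only the
#'   donor fluorophore (`s_dd > 0`).
#' @param acceptor_only A [fret_acquisition()] of a sample containing only the
#'   acceptor fluorophore (`s_aa > 0`).
#' @param gamma Brightness factor supplied by the caller (default 1).
#' @return A [correction_factors()] object.
#' @examples
#' d <- fret_acquisition(s_dd = 500, s_da = 50, state = "on")
#' a <- fret_acquisition(s_dd = 1, s_da = 20, s_aa = 400, state = "on")
#' estimate_crosstalk(d, a)
#' @export
estimate_crosstalk <- function(donor_only, acceptor_only, gamma = 1) {
  stopifnot(inherits(donor_only, "fret_acquisition"),
            inherits(acceptor_only, "fret_acquisition"))
  if (!is.finite(donor_only$s_dd) || donor_only$s_dd <= 0) {
    stop_pcfret("donor-only control has s_dd <= 0; cannot estimate alpha",
                "pcfret_invalid_control")
  }
  if (is.na(acceptor_only$s_aa) || acceptor_only$s_aa <= 0) {
    stop_pcfret("acceptor-only control has s_aa missing or <= 0; cannot estimate delta",
                "pcfret_invalid_control")
  }
  correction_factors(alpha = donor_only$s_da / donor_only$s_dd,
                     delta = acceptor_only$s_da / acceptor_only$s_aa,
                     gamma = gamma)
}

#' Raw emission ratio
#'
#' The uncorrected ratio `R = s_da / s_dd` of acceptor to donor emission under
#' donor excitation.  It tracks relative FRET changes without requiring any
#' correction factors.
#'
#' @param acq A [fret_acquisition()] with `s_dd > 0`.
#' @return The dimensionless emission ratio.
#' @export
emission_ratio <- function(acq) {
  stopifnot(inherits(acq, "fret_acquisition"))
  if (acq$s_dd <= 0) {
    stop_pcfret("s_dd must be > 0 to form an emission ratio",
                "pcfret_degenerate")
  }
  acq$s_da / acq$s_dd
}

#' Sensitized emission
#'
#' The donor-excited acceptor emission corrected for donor bleed-through and
#' direct acceptor excitation: `F_c = s_da - alpha * s_dd - delta * s_aa`.
#' Photon noise can drive `F_c` negative; the value is reported as-is so that
#' downstream fits see unbiased noise.  Clipping (if desired) is a caller
#' policy; [fret_efficiency()] clips only at the efficiency boundary.
#'
#' @param acq A [fret_acquisition()].  `s_aa` is required when `delta > 0`.
#' @param cf A [correction_factors()] object.
#' @return The sensitized emission intensity (may be negative).
#' @examples
#' acq <- fret_acquisition(s_dd = 100, s_da = 120, s_aa = 200, state = "on")
#' sensitized_emission(acq, correction_factors(alpha = 0.1, delta = 0.05))
#' @export
sensitized_emission <- function(acq, cf) {
  stopifnot(inherits(acq, "fret_acquisition"), inherits(cf, "correction_factors"))
  if (cf$delta > 0 && is.na(acq$s_aa)) {
    stop_pcfret("s_aa is required when delta > 0 (direct excitation correction)",
                "pcfret_missing_channel")
  }
  saa_term <- if (cf$delta > 0) cf$delta * acq$s_aa else 0
  acq$s_da - cf$alpha * acq$s_dd - saa_term
}

#' FRET efficiency from sensitized emission
#'
#' Converts a corrected sensitized emission `f_c` and donor emission `s_dd`
#' into an absolute FRET efficiency using the brightness factor `gamma`:
#' `theta = 1 / (gamma * s_dd / f_c + 1)`.  Nonpositive `f_c` (possible under
#' photon noise) yields `theta = 0` with a warning of class
#' `"pcfret_clipped"`; the returned vector carries a logical `"clipped"`
#' attribute marking those entries.
#'
#' @param f_c Sensitized emission (vectorised).
#' @param s_dd Donor emission, `> 0` (vectorised, recycled).
#' @param gamma Brightness factor, `> 0`.
#' @return FRET efficiencies in `[0, 1]`, with attribute `"clipped"`.
#' @seealso [sensitized_from_efficiency()] for the inverse map.
#' @examples
#' fret_efficiency(100, 100, gamma = 1)  # 0.5
#' fret_efficiency(100, 100, gamma = 2)  # 1/3
#' @export
fret_efficiency <- function(f_c, s_dd, gamma = 1) {
  if (any(!is.finite(s_dd)) || any(s_dd <= 0)) {
    stop_pcfret("s_dd must be finite and > 0", "pcfret_degenerate")
  }
  .assert_scalar_num(gamma, "gamma")
  if (gamma <= 0) stop_pcfret("gamma must be > 0", "pcfret_invalid_input")
  theta <- .theta_from_signals(f_c, s_dd, gamma)
  clipped <- f_c <= 0
  if (any(clipped)) {
    warning(warningCondition(
      sprintf("%d nonpositive sensitized emission value(s); efficiency clipped to 0",
              sum(clipped)),
      class = "pcfret_clipped"))
  }
  attr(theta, "clipped") <- clipped
  theta
}

# Quiet vectorised core of Eq. for theta; theta = f_c / (gamma*s_dd + f_c),
# which is algebraically identical to 1/(gamma*s_dd/f_c + 1) but finite at
# f_c = 0 and s_dd = 0.
.theta_from_signals <- function(f_c, s_dd, gamma) {
  theta <- ifelse(f_c <= 0, 0, f_c / (gamma * s_dd + f_c))
  pmin(pmax(theta, 0), 1)
}

#' Sensitized emission expected for a given FRET efficiency
#'
#' Inverse of [fret_efficiency()]: `f_c = s_dd * gamma * theta / (1 - theta)`.
#' Used by the forward simulator and by the unmixing solver.
#'
#' @param theta FRET efficiency in `[0, 1)`.
#' @param s_dd Donor emission.
#' @param gamma Brightness factor, `> 0`.
#' @return Sensitized emission intensities.
#' @export
sensitized_from_efficiency <- function(theta, s_dd = 1, gamma = 1) {
  if (any(theta < 0 | theta >= 1)) {
    stop_pcfret("theta must lie in [0, 1)", "pcfret_invalid_input")
  }
  s_dd * gamma * theta / (1 - theta)
}

#' Sensitized emission ratio
#'
#' `R_c = f_c / s_dd`, the cross-talk-corrected counterpart of
#' [emission_ratio()].  Comparable across instruments and more sensitive to
#' FRET changes than the raw ratio, but not an absolute efficiency.
#'
#' @param f_c Sensitized emission.
#' @param s_dd Donor emission, `> 0`.
#' @return The dimensionless sensitized ratio.
#' @export
sensitized_ratio <- function(f_c, s_dd) {
  if (any(!is.finite(s_dd)) || any(s_dd <= 0)) {
    stop_pcfret("s_dd must be finite and > 0", "pcfret_degenerate")
  }
  f_c / s_dd
}

#' Fill unmeasured s_aa values by interpolation
#'
#' The directly excited acceptor signal is acquired at a reduced cadence to
#' limit acceptor photobleaching.  Because it varies slowly, missing
#' timepoints are filled by linear interpolation between measured frames,
#' with nearest-value extrapolation at the ends.
#'
#' @param time Numeric vector of acquisition times (seconds).
#' @param s_aa Numeric vector with `NA` at unmeasured timepoints.
#' @return `s_aa` with `NA`s replaced; all-`NA` input is returned unchanged.
#' @export
fill_saa <- function(time, s_aa) {
  stopifnot(length(time) == length(s_aa))
  ok <- !is.na(s_aa)
  if (!any(ok) || all(ok)) return(s_aa)
  if (sum(ok) == 1L) {
    s_aa[!ok] <- s_aa[ok]
    return(s_aa)
  }
  approx(time[ok], s_aa[ok], xout = time, rule = 2)$y
}
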