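#' Photochromic FRET pair model
#'
#' Bundles everything the unmixing solver needs to know about one FRET pair:
#' calibration models giving the donor- and acceptor-channel photoswitching
#' ratios as a function of the pair's FRET metric, plus the brightness
#' factor `gamma` used to convert recovered signals to an efficiency.
#'
#' A pair with a dark (non-fluorescent) acceptor is supported by passing
#' `acceptor_cal = NULL`; its acceptor-channel contribution is then treated
#' as identically zero (the placeholder ratio 1 multiplies a zero signal).
#'
#' @param pair_id Label for the pair.
#' @param donor_cal [calibration_model()] for the donor channel.
#' @param acceptor_cal [calibration_model()] for the acceptor channel, or
#'   `NULL` for a dark acceptor.
#' @param gamma Brightness factor, `> 0`.
#' @return An object of class `"pair_model"`.
#' @export
pair_model <- function(pair_id, donor_cal, acceptor_cal, gamma = 1) {
  stopifnot(inherits(donor_cal, "calibration_model"))
  if (!is.null(acceptor_cal)) {
    stopifnot(inherits(acceptor_cal, "calibration_model"))
    if (donor_cal$abscissa != acceptor_cal$abscissa) {
      stop_pcfret("donor and acceptor calibrations must share an abscissa",
                  "pcfret_invalid_input")
    }
  }
  .assert_scalar_num(gamma, "gamma")
  if (gamma <= 0) stop_pcfret("gamma must be > 0", "pcfret_invalid_input")
  structure(list(pair_id = as.character(pair_id), donor_cal = donor_cal,
                 acceptor_cal = acceptor_cal, gamma = as.numeric(gamma)),
            class = "pair_model")
}

#' Pair model for the single-species power-law regime
#'
#' Convenience constructor for a pair whose donor- and acceptor-channel
#' photoswitching both follow `rho0^(1 - theta)` (negligible or corrected
#' cross-talk, single species): the regime used throughout the simulation
#' study.
#'
#' @param pair_id Label.
#' @param rho0 No-FRET photoswitching ratio in `(0, 1]`.
#' @param gamma Brightness factor.
#' @param valid_range FRET-efficiency range covered.
#' @return A [pair_model()].
#' @export
power_law_pair <- function(pair_id, rho0, gamma = 1, valid_range = c(0, 0.6)) {
  cal <- function(channel) {
    calibration_model("power_law", c(rho0 = rho0), channel = channel,
                      valid_range = valid_range, abscissa = "theta")
  }
  pair_model(pair_id, cal("donor"), cal("acceptor"), gamma = gamma)
}

#' Solve the two-pair linear system for one on/off cycle
#'
#' The measured on- and off-state signals in each channel are sums of the
#' per-pair contributions, with the off-state contributions scaled by the
#' per-pair photoswitching ratios:
#' \deqn{S_{on} = S_{on,1} + S_{on,2}, \quad
#'       S_{off} = \rho_1 S_{on,1} + \rho_2 S_{on,2}}
#' per channel.  With all four ratios known this is a system of four
#' equations and four unknowns with the exact algebraic solution
#' `S_on1 = (S_off - rho2 * S_on) / (rho1 - rho2)` (no least squares).
#' Components may come out negative under noise; they are returned as-is.
#'
#' @param s_dd_on,s_dd_off,s_da_on,s_da_off Mixed channel intensities.
#' @param rho_d1,rho_d2 Donor-channel photoswitching ratios of pairs 1 and 2.
#' @param rho_a1,rho_a2 Acceptor-channel ratios.
#' @param singular_tol Minimum `|rho1 - rho2|` per channel; below it the
#'   system is noise-dominated and an error of class `"pcfret_unresolvable"`
#'   is thrown naming the offending channel.
#' @return List with numeric length-2 vectors `s_dd_on` and `s_da_on`
#'   (per-pair on-state signals).
#' @examples
#' solve_two_component(2000, 1300, 800, 500, 0.3, 1, 0.3, 1)
#' @export
solve_two_component <- function(s_dd_on, s_dd_off, s_da_on, s_da_off,
                                rho_d1, rho_d2, rho_a1, rho_a2,
                                singular_tol = 0.02) {
  list(s_dd_on = .solve_channel(s_dd_on, s_dd_off, rho_d1, rho_d2,
                                singular_tol, "donor"),
       s_da_on = .solve_channel(s_da_on, s_da_off, rho_a1, rho_a2,
                                singular_tol, "acceptor"))
}

.solve_channel <- function(s_on, s_off, rho1, rho2, singular_tol, channel) {
  if (abs(rho1 - rho2) < singular_tol) {
    stop_pcfret(sprintf(
      "%s channel unresolvable: |rho1 - rho2| = %.4g < %.4g",
      channel, abs(rho1 - rho2), singular_tol), "pcfret_unresolvable")
  }
  v1 <- (s_off - rho2 * s_on) / (rho1 - rho2)
  c(v1, s_on - v1)
}

#' Solve the n-pair linear system from an acquisition ladder
#'
#' With `n` pairs, each switching cycle records `n` acquisitions per channel:
#' one on-state read plus `n - 1` reads at progressive off-switching doses.
#' Writing `rho[k, i]` for the fraction of pair `i`'s on-state signal left at
#' acquisition `k` (row 1 is all ones), the measurements satisfy
#' `signals = rho %*% s_on` and the per-pair on-state signals follow from an
#' exact linear solve.  The condition number of `rho` is attached; above
#' `cond_max` the pairs are declared unresolvable.
#'
#' @param signals Numeric vector of `n` measured intensities in one channel
#'   (on first, then progressive off states).
#' @param rho `n x n` matrix of per-pair retention fractions (rows =
#'   acquisitions, columns = pairs; first row all 1).
#' @param cond_max Condition-number threshold.
#' @return Per-pair on-state signals with attribute `"condition_number"`.
#' @export
solve_n_component <- function(signals, rho, cond_max = 1e6) {
  rho <- as.matrix(rho)
  n <- length(signals)
  if (!all(dim(rho) == n)) {
    stop_pcfret("rho must be an n x n matrix matching length(signals)",
                "pcfret_invalid_input")
  }
  if (max(abs(rho[1, ] - 1)) > 1e-9) {
    stop_pcfret("first row of rho must be 1 (the on-state acquisition)",
                "pcfret_invalid_input")
  }
  kap <- kappa(rho, exact = TRUE)
  if (!is.finite(kap) || kap > cond_max) {
    stop_pcfret(sprintf(
      "pairs unresolvable: condition number %.3g exceeds %.3g", kap, cond_max),
      "pcfret_unresolvable")
  }
  out <- solve(rho, signals)
  attr(out, "condition_number") <- kap
  out
}

#' Iteratively unmix two photochromic FRET pairs
#'
#' The photoswitching ratios entering the linear system of
#' [solve_two_component()] themselves depend on the sought-after FRET
#' metrics.  Starting from initial guesses, the solver alternates between
#' (i) evaluating each pair's donor- and acceptor-channel ratios from its
#' calibration at the current metric, (ii) solving the linear system, and
#' (iii) recomputing each pair's metric from its recovered signals, until the
#' largest metric update falls below `tol`.  A damping factor of 0.5 is
#' applied to a pair's update when its sign alternates twice in a row
#' (oscillation guard).
#'
#' When correction factors are supplied, the acceptor-channel system is
#' solved on the sensitized emission `F_c` (corrected mode) and the
#' calibrations must have been measured the same way; otherwise the raw
#' `s_da` channel is used.  Negative recovered components are clipped to zero
#' (flagged), with the complement assigned to the other pair so per-channel
#' sums are conserved.
#'
#' @param on,off [fret_acquisition()] objects for one switching cycle.
#' @param pairs List of two [pair_model()] objects.
#' @param cf Optional [correction_factors()].
#' @param init Optional numeric length-2 initial metric guesses; default is
#'   the midpoint of each donor calibration's valid range.
#' @param tol Convergence tolerance on the largest metric update.
#' @param max_iter Iteration cap; non-convergence is reported in the result,
#'   not thrown.
#' @param theta_max Working-range cap keeping the efficiency-to-signal
#'   inversion finite inside the loop.
#' @param singular_tol Passed to [solve_two_component()].
#' @return A data frame of class `"unmix_result"` with one row per pair and
#'   columns `pair_id`, `s_dd_on`, `s_da_on`, `theta`, `clipped`, plus
#'   attributes `iterations`, `converged` and `residual` (last max update).
#' @examples
#' pairs <- list(power_law_pair("rsAKARev", 0.3), power_law_pair("EKARev", 1.0))
#' sim <- simulate_acquisition(
#'   list(pair_sim_spec(1e4, 0.3), pair_sim_spec(1e4, 1.0)),
#'   thetas = c(0.35, 0.10), noise = FALSE)
#' iterative_unmix(sim$on, sim$off, pairs)
#' @export
iterative_unmix <- function(on, off, pairs, cf = NULL, init = NULL,
                            tol = 1e-6, max_iter = 100, theta_max = 0.95,
                            singular_tol = 0.02) {
  stopifnot(inherits(on, "fret_acquisition"), inherits(off, "fret_acquisition"),
            length(pairs) == 2L)
  lapply(pairs, function(p) stopifnot(inherits(p, "pair_model")))
  abscissa <- pairs[[1]]$donor_cal$abscissa
  if (pairs[[2]]$donor_cal$abscissa != abscissa) {
    stop_pcfret("both pairs must use the same calibration abscissa",
                "pcfret_invalid_input")
  }

  d_on <- on$s_dd; d_off <- off$s_dd
  if (!is.null(cf)) {
    a_on <- sensitized_emission(on, cf)
    a_off <- sensitized_emission(off, cf)
  } else {
    a_on <- on$s_da; a_off <- off$s_da
  }

  metric <- if (is.null(init)) {
    vapply(pairs, function(p) mean(p$donor_cal$valid_range), numeric(1))
  } else {
    as.numeric(init)
  }
  gammas <- vapply(pairs, function(p) p$gamma, numeric(1))
  dark <- vapply(pairs, function(p) is.null(p$acceptor_cal), logical(1))

  prev_delta <- c(0, 0)
  osc <- c(0L, 0L)
  converged <- FALSE
  resid <- Inf
  iter <- 0L
  comp <- NULL
  clipped <- c(FALSE, FALSE)

  for (iter in seq_len(max_iter)) {
    rho_d <- vapply(seq_along(pairs), function(i)
      as.numeric(evaluate_calibration(pairs[[i]]$donor_cal, metric[i])),
      numeric(1))
    rho_a <- vapply(seq_along(pairs), function(i) {
      ac <- pairs[[i]]$acceptor_cal
      if (is.null(ac)) 1 else as.numeric(evaluate_calibration(ac, metric[i]))
    }, numeric(1))

    dd_comp <- .solve_channel(d_on, d_off, rho_d[1], rho_d[2],
                              singular_tol, "donor")
    # a dark acceptor contributes nothing to the acceptor channel: the
    # whole signal belongs to the fluorescent-acceptor pair(s)
    da_comp <- if (any(dark)) {
      da <- c(0, 0)
      if (any(!dark)) da[!dark] <- a_on
      da
    } else {
      .solve_channel(a_on, a_off, rho_a[1], rho_a[2],
                     singular_tol, "acceptor")
    }
    comp <- list(s_dd_on = dd_comp, s_da_on = da_comp)
    # clip negative components, assigning the complement to the other pair
    # so per-channel sums stay conserved
    clipped <- c(FALSE, FALSE)
    for (ch in c("s_dd_on", "s_da_on")) {
      v <- comp[[ch]]
      neg <- v < 0
      if (any(neg)) {
        tot <- sum(v)
        v[neg] <- 0
        v[!neg] <- max(tot, 0)
        comp[[ch]] <- v
        clipped <- clipped | neg
      }
    }

    new_metric <- vapply(seq_along(pairs), function(i) {
      s_dd_i <- comp$s_dd_on[i]; f_c_i <- comp$s_da_on[i]
      if (abscissa == "theta") {
        min(.theta_from_signals(f_c_i, max(s_dd_i, 0), gammas[i]), theta_max)
      } else {
        if (s_dd_i <= 0) 0 else max(f_c_i, 0) / s_dd_i
      }
    }, numeric(1))

    delta <- new_metric - metric
    osc <- ifelse(sign(delta) != 0 & sign(delta) == -sign(prev_delta),
                  osc + 1L, 0L)
    damp <- ifelse(osc >= 2L, 0.5, 1)
    metric <- metric + damp * delta
    prev_delta <- delta
    resid <- max(abs(delta))
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }

  theta <- vapply(seq_along(pairs), function(i)
    .theta_from_signals(comp$s_da_on[i], max(comp$s_dd_on[i], 0), gammas[i]),
    numeric(1))
  res <- data.frame(pair_id = vapply(pairs, `[[`, "", "pair_id"),
                    s_dd_on = comp$s_dd_on, s_da_on = comp$s_da_on,
                    theta = theta, clipped = clipped,
                    stringsAsFactors = FALSE)
  attr(res, "iterations") <- iter
  attr(res, "converged") <- converged
  attr(res, "residual") <- resid
  class(res) <- c("unmix_result", "data.frame")
  res
}

#' Unmix a time series of paired on/off acquisitions
#'
#' Applies [iterative_unmix()] to each switching cycle of a trace, warm-
#' starting every timepoint from the previous solution (the first timepoint
#' starts at the calibration-range midpoints).  The input is a per-ROI trace
#' table as read by [read_trace_csv()]: alternating `on`/`off` rows with
#' columns `time_s, state, s_dd, s_da, s_aa`.  Missing `s_aa` values are
#' filled with [fill_saa()] before cross-talk correction.
#'
#' @param trace Data frame with columns `time_s`, `state`, `s_dd`, `s_da`,
#'   and optionally `s_aa`.
#' @param pairs List of two [pair_model()] objects.
#' @param cf Optional [correction_factors()].
#' @param ... Passed to [iterative_unmix()].
#' @return Data frame with columns `time_s, pair_id, s_dd_on, s_da_on,
#'   theta, converged, iterations` (two rows per cycle).
#' @export
unmix_timeseries <- function(trace, pairs, cf = NULL, ...) {
  cols <- c("time_s", "state", "s_dd", "s_da")
  missing_cols <- setdiff(cols, names(trace))
  if (length(missing_cols)) {
    stop_pcfret(paste("trace is missing column(s):",
                      paste(missing_cols, collapse = ", ")),
                "pcfret_parse_error")
  }
  if (nrow(trace) == 0L) {
    return(data.frame(time_s = numeric(0), pair_id = character(0),
                      s_dd_on = numeric(0), s_da_on = numeric(0),
                      theta = numeric(0), converged = logical(0),
                      iterations = integer(0), stringsAsFactors = FALSE))
  }
  if (!"s_aa" %in% names(trace)) trace$s_aa <- NA_real_
  trace$s_aa <- fill_saa(trace$time_s, trace$s_aa)
  is_on <- trace$state == "on"
  if (!all(is_on == rep(c(TRUE, FALSE), length.out = nrow(trace))) ) {
    stop_pcfret("trace rows must alternate on/off, starting with 'on'",
                "pcfret_parse_error")
  }
  n_cyc <- nrow(trace) %/% 2L
  out <- vector("list", n_cyc)
  guess <- NULL
  for (k in seq_len(n_cyc)) {
    r_on <- trace[2L * k - 1L, ]; r_off <- trace[2L * k, ]
    on <- fret_acquisition(r_on$s_dd, r_on$s_da, r_on$s_aa, "on", r_on$time_s)
    off <- fret_acquisition(r_off$s_dd, r_off$s_da, r_off$s_aa, "off", r_off$time_s)
    res <- iterative_unmix(on, off, pairs, cf = cf, init = guess, ...)
    guess <- res$theta
    out[[k]] <- data.frame(time_s = r_on$time_s, pair_id = res$pair_id,
                           s_dd_on = res$s_dd_on, s_da_on = res$s_da_on,
                           theta = res$theta,
                           converged = attr(res, "converged"),
                           iterations = attr(res, "iterations"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Brute-force grid-search unmixing
#'
#' Independent cross-check for [iterative_unmix()]: for every candidate
#' efficiency pair on a grid, the two on-state donor amplitudes are the
#' least-squares solution of the full forward model (on- and off-state
#' predictions in both channels), and the candidate minimising the residual
#' is returned.  Much slower than the fixed-point solver, but makes no use
#' of it.
#'
#' @param on,off [fret_acquisition()] objects (cross-talk-free or already
#'   corrected signals).
#' @param pairs List of two [pair_model()] objects with `"theta"` abscissa.
#' @param grid Numeric vector of candidate efficiencies for each pair.
#' @return List with `theta` (length-2 estimate) and `residual`.
#' @export
unmix_grid_search <- function(on, off, pairs,
                              grid = seq(0, 0.6, length.out = 61)) {
  g <- expand.grid(t1 = grid, t2 = grid)
  gam <- vapply(pairs, function(p) p$gamma, numeric(1))
  # per-candidate forward-model coefficients
  g1 <- gam[1] * g$t1 / (1 - g$t1); g2 <- gam[2] * g$t2 / (1 - g$t2)
  r1 <- as.numeric(evaluate_calibration(pairs[[1]]$donor_cal, g$t1))
  r2 <- as.numeric(evaluate_calibration(pairs[[2]]$donor_cal, g$t2))
  ra1 <- if (is.null(pairs[[1]]$acceptor_cal)) rep(1, nrow(g)) else
    as.numeric(evaluate_calibration(pairs[[1]]$acceptor_cal, g$t1))
  ra2 <- if (is.null(pairs[[2]]$acceptor_cal)) rep(1, nrow(g)) else
    as.numeric(evaluate_calibration(pairs[[2]]$acceptor_cal, g$t2))
  s <- c(on$s_dd, on$s_da, off$s_dd, off$s_da)
  # rows of the 4x2 design: donor on, acceptor on, donor off, acceptor off
  m11 <- 1;        m12 <- 1
  m21 <- g1;       m22 <- g2
  m31 <- r1;       m32 <- r2
  m41 <- ra1 * g1; m42 <- ra2 * g2
  # normal equations, vectorised over candidates (tiny ridge for rank safety)
  a11 <- m11^2 + m21^2 + m31^2 + m41^2 + 1e-12
  a22 <- m12^2 + m22^2 + m32^2 + m42^2 + 1e-12
  a12 <- m11 * m12 + m21 * m22 + m31 * m32 + m41 * m42
  b1 <- m11 * s[1] + m21 * s[2] + m31 * s[3] + m41 * s[4]
  b2 <- m12 * s[1] + m22 * s[2] + m32 * s[3] + m42 * s[4]
  det <- a11 * a22 - a12^2
  n1 <- (a22 * b1 - a12 * b2) / det
  n2 <- (a11 * b2 - a12 * b1) / det
  n1 <- pmax(n1, 0); n2 <- pmax(n2, 0)
  resid <- (m11 * n1 + m12 * n2 - s[1])^2 + (m21 * n1 + m22 * n2 - s[2])^2 +
    (m31 * n1 + m32 * n2 - s[3])^2 + (m41 * n1 + m42 * n2 - s[4])^2
  i <- which.min(resid)
  list(theta = c(g$t1[i], g$t2[i]), residual = resid[i])
}
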