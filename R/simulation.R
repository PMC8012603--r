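#' Simulation specification for one FRET pair
#'
#' `brightness_n` is the expected number of photons detected in the on-state
#' donor channel if the pair showed no FRET; energy transfer moves a
#' `gamma`-scaled share of those photons into the acceptor channel (photon
#' totals are conserved at `gamma = 1`).  `rho0` is the donor photoswitching
#' ratio in the absence of FRET (1 for a photostatic donor).
#'
#' @param brightness_n Expected on-state photons at zero FRET, `>= 0`.
#' @param rho0 No-FRET photoswitching ratio in `(0, 1]`.
#' @param gamma Brightness factor.
#' @return An object of class `"pair_sim_spec"`.
#' @export
pair_sim_spec <- function(brightness_n, rho0, gamma = 1) {
  .assert_scalar_num(brightness_n, "brightness_n")
  .assert_scalar_num(rho0, "rho0")
  if (brightness_n < 0) {
    stop_pcfret("brightness_n must be >= 0", "pcfret_invalid_input")
  }
  if (rho0 <= 0 || rho0 > 1) {
    stop_pcfret("rho0 must lie in (0, 1]", "pcfret_invalid_input")
  }
  structure(list(brightness_n = as.numeric(brightness_n),
                 rho0 = as.numeric(rho0), gamma = as.numeric(gamma)),
            class = "pair_sim_spec")
}

#' Simulate one paired on/off acquisition of a two-pair mixture
#'
#' Forward model of the measurement scheme: for each pair `i` with
#' brightness `N_i`, efficiency `theta_i` and no-FRET switching ratio
#' `rho0_i`, the expected on-state signals are
#' `E[S_DD,i] = N_i (1 - theta_i)` and `E[S_DA,i] = gamma_i N_i theta_i`;
#' off-state expectations scale by `rho_i = rho0_i^(1 - theta_i)` in both
#' channels (single-species regime).  Each of the four observed channel
#' values is an independent Poisson draw around the summed expectations;
#' cross-talk is zero (`alpha = delta = 0`), so `s_da` equals the sensitized
#' emission.
#'
#' @param pairs List of two [pair_sim_spec()] objects.
#' @param thetas Ground-truth efficiencies in `[0, 1)`, one per pair.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param noise If `FALSE`, return the noise-free expectations
#'   ("expectation mode").
#' @param n_reads Number of independent Poisson reads averaged per state
#'   (extra fluorescence acquisitions during the switching cycle).
#' @return List with `on` and `off` [fret_acquisition()] objects.
#' @examples
#' specs <- list(pair_sim_spec(1000, 0.3), pair_sim_spec(1000, 1.0))
#' simulate_acquisition(specs, c(0.35, 0.10), seed = 1)
#' @export
simulate_acquisition <- function(pairs, thetas, seed = NULL, noise = TRUE,
                                 n_reads = 1L) {
  stopifnot(length(pairs) == 2L, length(thetas) == 2L)
  lapply(pairs, function(p) stopifnot(inherits(p, "pair_sim_spec")))
  if (any(thetas < 0 | thetas >= 1)) {
    stop_pcfret("thetas must lie in [0, 1)", "pcfret_invalid_input")
  }
  n <- vapply(pairs, `[[`, numeric(1), "brightness_n")
  g <- vapply(pairs, `[[`, numeric(1), "gamma")
  r0 <- vapply(pairs, `[[`, numeric(1), "rho0")
  rho <- r0^(1 - thetas)
  dd_on <- n * (1 - thetas)
  da_on <- g * n * thetas
  mu <- c(dd_on = sum(dd_on), da_on = sum(da_on),
          dd_off = sum(rho * dd_on), da_off = sum(rho * da_on))
  obs <- if (noise) {
    draw <- function() {
      rowMeans(matrix(rpois(4L * n_reads, mu), nrow = 4L))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else {
    mu
  }
  list(on = fret_acquisition(obs[1], obs[2], state = "on"),
       off = fret_acquisition(obs[3], obs[4], state = "off"))
}

#' Mean absolute deviation between true and estimated efficiency pairs
#'
#' `(|theta1 - theta1_hat| + |theta2 - theta2_hat|) / 2`, the accuracy metric
#' of the simulation study.  (Named `mad_theta` to avoid masking
#' [stats::mad()].)
#'
#' @param theta_true,theta_est Numeric length-2 vectors.
#' @return A nonnegative scalar.
#' @export
mad_theta <- function(theta_true, theta_est) {
  stopifnot(length(theta_true) == 2L, length(theta_est) == 2L)
  if (any(!is.finite(c(theta_true, theta_est)))) {
    stop_pcfret("all efficiencies must be finite", "pcfret_invalid_input")
  }
  mean(abs(theta_true - theta_est))
}

.study_summary <- function(mads) {
  mads <- mads[is.finite(mads)]
  if (!length(mads)) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             whisker_lo = NA_real_, whisker_hi = NA_real_))
  }
  q <- quantile(mads, c(0.25, 0.5, 0.75), names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(mads), whisker_hi = max(mads))
}

.study_result <- function(label, mads, n_failed, details = NULL) {
  structure(list(label = label, mad_samples = mads, n_failed = n_failed,
                 summary = .study_summary(mads), details = details),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s: n=%d, failed=%d, median MAD=%.4g\n",
              x$label, length(x$mad_samples), x$n_failed,
              x$summary[["median"]]))
  invisible(x)
}

#' Run a Monte-Carlo unmixing accuracy study
#'
#' For each condition, repeatedly draws ground-truth efficiencies uniformly
#' from `theta_range`, simulates one paired on/off acquisition with
#' [simulate_acquisition()], unmixes it with [iterative_unmix()] using the
#' exact power-law calibrations implied by the pair specs, and records the
#' [mad_theta()] between truth and estimate.  Solver failures are recorded
#' as `NA` with a count and never abort the study.
#'
#' @param conditions List of condition lists, each with elements `pairs`
#'   (two [pair_sim_spec()]), `n_sims`, and optionally `theta_range`
#'   (default `c(0, 0.6)`), `noise` (default `TRUE`), `n_reads` and `label`.
#' @param seed Integer seed making the whole study reproducible.
#' @return A list of `"study_result"` objects, one per condition, each with
#'   `mad_samples`, `n_failed`, and a `summary` (median, quartiles, whisker
#'   range).
#' @export
run_study <- function(conditions, seed = 1L) {
  withr::with_seed(seed, lapply(seq_along(conditions), function(ci) {
    cond <- conditions[[ci]]
    pairs <- cond$pairs
    n_sims <- cond$n_sims
    theta_range <- cond$theta_range %||% c(0, 0.6)
    noise <- cond$noise %||% TRUE
    n_reads <- cond$n_reads %||% 1L
    label <- cond$label %||% paste0("condition_", ci)
    stopifnot(n_sims >= 1L)
    models <- lapply(seq_along(pairs), function(i)
      power_law_pair(paste0("pair", i), pairs[[i]]$rho0,
                     gamma = pairs[[i]]$gamma, valid_range = theta_range))
    details <- data.frame(sim_idx = seq_len(n_sims),
                          theta1 = NA_real_, theta2 = NA_real_,
                          theta1_hat = NA_real_, theta2_hat = NA_real_,
                          mad = NA_real_, converged = NA)
    n_failed <- 0L
    for (s in seq_len(n_sims)) {
      th <- runif(2L, theta_range[1], theta_range[2])
      details$theta1[s] <- th[1]; details$theta2[s] <- th[2]
      acq <- simulate_acquisition(pairs, th, noise = noise, n_reads = n_reads)
      est <- tryCatch(
        iterative_unmix(acq$on, acq$off, models),
        pcfret_error = function(e) NULL)
      if (is.null(est)) {
        n_failed <- n_failed + 1L
      } else {
        details$theta1_hat[s] <- est$theta[1]
        details$theta2_hat[s] <- est$theta[2]
        details$converged[s] <- attr(est, "converged")
        details$mad[s] <- mad_theta(th, est$theta)
      }
    }
    .study_result(label, details$mad, n_failed, details)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-guess negative control for the accuracy study
#'
#' Distribution of [mad_theta()] between independent uniform draws over
#' `theta_range` — what an "analysis" that guesses efficiencies at random
#' would score.  For `theta_range = c(0, 0.6)` the mean MAD tends to
#' `(0.6 - 0) / 3 = 0.2`.
#'
#' @param theta_range Efficiency range.
#' @param n_sims Number of draws (0 gives an empty result).
#' @param seed Integer seed.
#' @return A `"study_result"`.
#' @export
random_guess_control <- function(theta_range = c(0, 0.6), n_sims = 5000L,
                                 seed = 1L) {
  if (n_sims == 0L) return(.study_result("random_guess", numeric(0), 0L))
  mads <- withr::with_seed(seed, {
    tru <- matrix(runif(2L * n_sims, theta_range[1], theta_range[2]), ncol = 2L)
    gue <- matrix(runif(2L * n_sims, theta_range[1], theta_range[2]), ncol = 2L)
    rowMeans(abs(tru - gue))
  })
  .study_result("random_guess", mads, 0L)
}
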