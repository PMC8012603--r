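#' Construct a per-ROI time trace
#'
#' A time-indexed sequence of values (channel intensity, FRET efficiency, or
#' percent increase) for one region of interest, with an optional per-
#' timepoint flag (e.g. floored background-corrected intensities).
#'
#' @param time Strictly increasing times in seconds.
#' @param value Numeric values, same length as `time`.
#' @param roi_id Label.
#' @param flag Logical per-timepoint flags.
#' @return An object of class `"cell_trace"`.
#' @export
cell_trace <- function(time, value, roi_id = "roi",
                       flag = rep(FALSE, length(time))) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value) || length(flag) != length(time)) {
    stop_pcfret("time, value and flag must have equal length",
                "pcfret_invalid_input")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_pcfret("time must be strictly increasing", "pcfret_invalid_input")
  }
  structure(list(time = time, value = value, roi_id = as.character(roi_id),
                 flag = as.logical(flag)),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %s: %d timepoints over [%g, %g] s\n",
              x$roi_id, length(x$time),
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA))
  invisible(x)
}

#' Extract background-corrected per-ROI mean intensity traces
#'
#' For each labelled region, the mean intensity over the region is computed
#' at every frame and the per-frame mean of a background region (outside all
#' cells) is subtracted.  Negative corrected values are floored at 0 and
#' flagged.
#'
#' @param stack Numeric 3-D array (`rows x cols x frames`) or a list of
#'   equally sized matrices, one per frame.
#' @param rois Integer label matrix (0 = unlabelled) matching the frame
#'   geometry; each positive label is one cell ROI.
#' @param background_roi Logical matrix selecting the background region;
#'   must be disjoint from all cell ROIs and non-empty.
#' @param time Optional acquisition times (seconds); defaults to the frame
#'   index.
#' @return Named list of [cell_trace()] objects, one per ROI label.
#' @export
extract_roi_traces <- function(stack, rois, background_roi, time = NULL) {
  if (is.list(stack)) {
    stack <- simplify2array(stack)
  }
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L) {
    stop_pcfret("stack must be a rows x cols x frames array",
                "pcfret_invalid_input")
  }
  n_frames <- dim(stack)[3]
  if (n_frames == 0L) {
    stop_pcfret("stack has no frames", "pcfret_missing_frames")
  }
  rois <- as.matrix(rois)
  background_roi <- as.matrix(background_roi)
  if (!all(dim(rois) == dim(stack)[1:2]) ||
      !all(dim(background_roi) == dim(stack)[1:2])) {
    stop_pcfret("ROI masks must match the image geometry",
                "pcfret_invalid_input")
  }
  bg_mask <- as.logical(background_roi)
  if (!any(bg_mask)) {
    stop_pcfret("background ROI is empty", "pcfret_empty_roi")
  }
  if (any(bg_mask & rois > 0)) {
    stop_pcfret("background ROI overlaps a cell ROI", "pcfret_invalid_input")
  }
  labels <- sort(unique(rois[rois > 0]))
  if (is.null(time)) time <- seq_len(n_frames)
  if (length(time) != n_frames) {
    stop_pcfret("time must have one entry per frame", "pcfret_missing_frames")
  }
  frames <- matrix(stack, ncol = n_frames)  # pixels x frames
  bg <- colMeans(frames[bg_mask, , drop = FALSE])
  out <- lapply(labels, function(lab) {
    mask <- as.logical(rois == lab)
    if (!any(mask)) stop_pcfret("empty ROI", "pcfret_empty_roi")
    v <- colMeans(frames[mask, , drop = FALSE]) - bg
    flag <- v < 0
    v[flag] <- 0
    cell_trace(time, v, roi_id = as.character(lab), flag = flag)
  })
  names(out) <- as.character(labels)
  out
}

# Bounded Levenberg-Marquardt least squares on a residual function; returns
# the named coefficient vector, or NULL when the optimiser reports failure.
.lm_fit <- function(resid_fn, start, lower, upper) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(res) || !(res$info %in% 1:4)) return(NULL)
  res$par
}

#' Fit a photobleaching baseline to a trace
#'
#' FRET-efficiency traces decay slowly through photobleaching of the
#' fluorophores.  For `kind = "sigmoid_exp"` the whole trace is fitted with
#' \deqn{\Theta(t) = e^{-t/\tau} (b + A / (1 + \exp((t_0 - t)/r)))}
#' (an exponential decay times a standard sigmoidal response) and the
#' baseline is the decay-only part `b * exp(-t / tau)`; `tau` is typically
#' much larger than the experiment.  For `kind = "biexponential"` (intensity
#' sensors such as RCaMP, whose responses are not sigmoidal) a
#' bi-exponential `a1 * exp(-t/tau1) + a2 * exp(-t/tau2)` is fitted to the
#' quiet parts of the trace only — the user-supplied intervals without an
#' elevated signal — and evaluated everywhere.
#'
#' `tau` is bounded below by one tenth of the trace duration to exclude
#' degenerate fast decays.
#'
#' @param trace A [cell_trace()] with at least 8 timepoints.
#' @param kind `"sigmoid_exp"` or `"biexponential"`.
#' @param quiet_intervals For `"biexponential"`: list of `c(start, end)`
#'   half-open intervals (seconds) without elevated signal.
#' @return An object of class `"baseline_fit"`: `kind`, named `params`, the
#'   fitted-model evaluator `model(t)`, and `baseline(t)`.
#' @export
fit_baseline <- function(trace, kind = c("sigmoid_exp", "biexponential"),
                         quiet_intervals = NULL) {
  stopifnot(inherits(trace, "cell_trace"))
  kind <- match.arg(kind)
  t <- trace$time; y <- trace$value
  if (length(t) < 8L) {
    stop_pcfret("baseline fitting needs at least 8 timepoints",
                "pcfret_invalid_input")
  }
  dur <- diff(range(t))

  if (kind == "sigmoid_exp") {
    b0 <- max(median(head(y, max(3L, length(y) %/% 5L))), 1e-6)
    a0 <- max(max(y) - b0, 0.05 * b0)
    dy <- diff(y)
    t00 <- t[which.max(c(dy, 0))]
    # internally parametrised with the decay rate k = 1/tau so that a
    # non-decaying trace (k = 0) lies inside the parameter space; the
    # tau >= duration/10 bound becomes k <= 10/duration
    full <- .lm_fit(
      function(p) y - exp(-p[1] * t) * (p[2] + p[3] / (1 + exp((p[4] - t) / p[5]))),
      start = c(k = 1 / (dur * 10), b = b0, A = a0, t0 = t00, r = dur / 50),
      lower = c(0, 1e-12, 0, min(t) - dur, dur / 1e4),
      upper = c(10 / dur, Inf, Inf, max(t) + dur, dur))
    if (is.null(full)) {
      # degenerate responses (flat or response-free traces): decay only
      dec <- .lm_fit(function(p) y - p[2] * exp(-p[1] * t),
                     start = c(k = 1 / (dur * 10), b = b0),
                     lower = c(0, 1e-12), upper = c(10 / dur, Inf))
      if (is.null(dec)) {
        stop_pcfret("sigmoid_exp baseline fit did not converge",
                    "pcfret_fit_failure")
      }
      p <- c(tau = 1 / max(dec[["k"]], 1e-300), b = dec[["b"]],
             A = 0, t0 = min(t), r = dur / 50)
    } else {
      p <- c(tau = 1 / max(full[["k"]], 1e-300), b = full[["b"]],
             A = full[["A"]], t0 = full[["t0"]], r = full[["r"]])
    }
    model <- function(tt) {
      exp(-tt / p[["tau"]]) *
        (p[["b"]] + p[["A"]] / (1 + exp((p[["t0"]] - tt) / p[["r"]])))
    }
    baseline <- function(tt) p[["b"]] * exp(-tt / p[["tau"]])
  } else {
    if (is.null(quiet_intervals)) {
      stop_pcfret("biexponential baseline requires quiet_intervals",
                  "pcfret_invalid_input")
    }
    sel <- Reduce(`|`, lapply(quiet_intervals, function(iv)
      t >= iv[1] & t < iv[2]))
    if (sum(sel) < 8L) {
      stop_pcfret("quiet intervals cover fewer than 8 timepoints",
                  "pcfret_invalid_input")
    }
    tq <- t[sel]; yq <- y[sel]
    y0 <- max(mean(yq), 1e-6)
    p <- .lm_fit(
      function(p) yq - p[1] * exp(-tq / p[2]) - p[3] * exp(-tq / p[4]),
      start = c(a1 = 0.7 * y0, tau1 = dur * 5, a2 = 0.3 * y0, tau2 = dur),
      lower = c(0, dur / 10, 0, dur / 10),
      upper = rep(Inf, 4))
    if (is.null(p)) {
      stop_pcfret("biexponential baseline fit did not converge",
                  "pcfret_fit_failure")
    }
    model <- function(tt) {
      p[["a1"]] * exp(-tt / p[["tau1"]]) + p[["a2"]] * exp(-tt / p[["tau2"]])
    }
    baseline <- model
  }
  structure(list(kind = kind, params = p, model = model, baseline = baseline),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s: %s\n", x$kind,
              paste(sprintf("%s=%.6g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Percent increase of a trace over its baseline
#'
#' `(signal(t) - baseline(t)) / baseline(t) * 100`, the bleaching-corrected
#' response metric.  Invariant under rescaling signal and baseline by the
#' same positive constant.
#'
#' @param trace A [cell_trace()] (FRET efficiency or intensity).
#' @param baseline A [fit_baseline()] result, a function of time, or a
#'   numeric vector matching the trace; must be `> 0` on the trace domain.
#' @return A [cell_trace()] of percent values.
#' @export
percent_increase <- function(trace, baseline) {
  stopifnot(inherits(trace, "cell_trace"))
  b <- if (inherits(baseline, "baseline_fit")) {
    baseline$baseline(trace$time)
  } else if (is.function(baseline)) {
    baseline(trace$time)
  } else {
    as.numeric(baseline)
  }
  if (length(b) != length(trace$time)) {
    stop_pcfret("baseline length does not match the trace",
                "pcfret_invalid_input")
  }
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop_pcfret("baseline must be positive over the trace domain",
                "pcfret_invalid_input")
  }
  cell_trace(trace$time, (trace$value - b) / b * 100,
             roi_id = trace$roi_id, flag = trace$flag)
}

#' Maximum response within a stimulation interval
#'
#' The maximum of the percent-increase response over the half-open interval
#' `[start, end)` following a stimulation.  By definition this is the signed
#' maximum: an all-negative response yields its (negative) maximum, not 0.
#'
#' @param response A [cell_trace()] of percent increases.
#' @param interval `c(start, end)` in seconds.
#' @return The maximum response (percent).
#' @export
max_response <- function(response, interval) {
  stopifnot(inherits(response, "cell_trace"), length(interval) == 2L)
  sel <- response$time >= interval[1] & response$time < interval[2]
  if (!any(sel)) {
    stop_pcfret("interval does not overlap the trace domain",
                "pcfret_invalid_input")
  }
  max(response$value[sel])
}

#' Onset time of a response
#'
#' Two definitions are provided, matching the sensor types they are used
#' for:
#'
#' * `"sigmoid_7p6"` (FRET biosensors): a sigmoid
#'   `A / (1 + exp((t0 - t)/r))` is fitted to the response and the onset is
#'   the time at which it reaches 7.6% of its maximum,
#'   `t0 - r * log(1/0.076 - 1)`.
#' * `"second_derivative"` (intensity sensors): the time at which the
#'   smoothed discrete second derivative of the response is maximal, using a
#'   Savitzky-Golay local quadratic filter.
#'
#' @param response A [cell_trace()] (typically percent increase).
#' @param method `"sigmoid_7p6"` or `"second_derivative"`.
#' @param window Savitzky-Golay window length (odd, default 5 samples).
#' @return Onset time in seconds, or `NA` with attribute `flag = "no_rise"`
#'   when no detectable rise is present.
#' @export
onset_time <- function(response, method = c("sigmoid_7p6", "second_derivative"),
                       window = 5L) {
  stopifnot(inherits(response, "cell_trace"))
  method <- match.arg(method)
  t <- response$time; y <- response$value
  no_rise <- structure(NA_real_, flag = "no_rise")
  if (length(t) < 5L) return(no_rise)
  amp <- max(y) - min(y)
  if (!is.finite(amp) || amp <= max(1e-8, 1e-6 * max(abs(y), 1))) {
    return(no_rise)
  }

  if (method == "sigmoid_7p6") {
    dur <- diff(range(t))
    a0 <- max(y)
    t00 <- t[which.min(abs(y - a0 / 2))]
    p <- .lm_fit(function(p) y - p[1] / (1 + exp((p[2] - t) / p[3])),
                 start = c(A = a0, t0 = t00, r = dur / 20),
                 lower = c(0, min(t) - dur, dur / 1e4),
                 upper = c(Inf, max(t) + dur, Inf))
    if (is.null(p) || p[["A"]] <= 0) return(no_rise)
    unname(p[["t0"]] - p[["r"]] * log(1 / 0.076 - 1))
  } else {
    if (window %% 2L == 0L) window <- window + 1L
    if (length(y) < window) return(no_rise)
    dt <- median(diff(t))
    d2 <- signal::sgolayfilt(y, p = 2, n = window, m = 2) / dt^2
    # edge samples of the filter are extrapolations; ignore them
    core <- (window %/% 2L + 1L):(length(y) - window %/% 2L)
    t[core][which.max(d2[core])]
  }
}

#' Classify cellular responses by k-means
#'
#' Clusters cells by their maximal responses over the designated stimulation
#' intervals (one feature per sensor/interval).  Features are z-scored
#' before clustering; labels are canonicalised by descending cluster size
#' (ties broken by first occurrence).
#'
#' @param features Numeric matrix or data frame, cells in rows, one column
#'   per response feature.
#' @param k Number of classes.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @return Integer class labels (1 = largest class), with the fitted
#'   [stats::kmeans()] object as attribute `"kmeans"`.
#' @export
cluster_responses <- function(features, k, seed = 1L, nstart = 25L) {
  x <- as.matrix(features)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_pcfret("features must be finite numeric", "pcfret_invalid_input")
  }
  if (k > nrow(x)) {
    stop_pcfret("k exceeds the number of cells", "pcfret_invalid_input")
  }
  if (k == 1L) {
    return(structure(rep(1L, nrow(x)), kmeans = NULL))
  }
  # z-score; constant features stay at 0
  x <- apply(x, 2L, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (nrow(unique(x)) < k) {
    # fewer distinct points than classes: assign by distinct value
    u <- unique(x)
    lab <- match(apply(x, 1L, paste, collapse = ","),
                 apply(u, 1L, paste, collapse = ","))
    lab <- pmin(lab, k)
  } else {
    km <- withr::with_seed(seed, kmeans(x, centers = k, nstart = nstart))
    lab <- km$cluster
  }
  # canonicalise: 1 = largest cluster
  sizes <- table(lab)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  out <- unname(relabel[as.character(lab)])
  attr(out, "kmeans") <- if (exists("km", inherits = FALSE)) km else NULL
  out
}
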