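#' Specification for a synthetic two-pair imaging fixture
#'
#' Describes a synthetic wide-field experiment in which every cell expresses
#' two spectrally identical FRET pairs with planted efficiency trajectories.
#' The per-pixel forward model is the same as [simulate_acquisition()]:
#' on-state expectations `N (1 - theta)` (donor channel) and
#' `gamma N theta` (acceptor channel) per pair, off-state expectations
#' scaled by `rho0^(1 - theta)`, summed over pairs, on a uniform background
#' offset, with optional per-pixel Poisson noise and a global
#' photobleaching decay `exp(-t / bleach_tau)`.
#'
#' @param dim Image geometry `c(rows, cols)`.
#' @param cells Data frame with columns `row`, `col`, `radius` (pixels), one
#'   row per cell; may have zero rows.
#' @param theta1,theta2 Matrices (`n_cells x n_timepoints`) of planted
#'   efficiencies per pair, or vectors for a single cell.
#' @param brightness Expected per-pixel on-state photons at zero FRET, per
#'   pair.
#' @param rho0 Length-2 no-FRET photoswitching ratios of the two donors.
#' @param gamma Brightness factor.
#' @param bg_level Uniform background offset (counts).
#' @param bleach_tau Photobleaching time constant (seconds; `Inf` disables).
#' @param noise `"none"` or `"poisson"`.
#' @param dt Cycle interval in seconds.
#' @param seed Integer seed.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(dim = c(48, 48),
                         cells = data.frame(row = 24, col = 24, radius = 8),
                         theta1, theta2,
                         brightness = 4000, rho0 = c(0.3, 1.0), gamma = 1,
                         bg_level = 0, bleach_tau = Inf,
                         noise = c("none", "poisson"), dt = 30, seed = 1L) {
  noise <- match.arg(noise)
  theta1 <- rbind(theta1); theta2 <- rbind(theta2)
  if (nrow(theta1) != nrow(cells) || nrow(theta2) != nrow(cells) ||
      ncol(theta1) != ncol(theta2)) {
    stop_pcfret("theta1/theta2 must be n_cells x n_timepoints",
                "pcfret_invalid_input")
  }
  if (length(theta1) && (any(theta1 < 0 | theta1 >= 1) ||
                         any(theta2 < 0 | theta2 >= 1))) {
    stop_pcfret("planted efficiencies must lie in [0, 1)",
                "pcfret_invalid_input")
  }
  structure(list(dim = as.integer(dim), cells = cells, theta1 = theta1,
                 theta2 = theta2, brightness = brightness,
                 rho0 = as.numeric(rho0), gamma = gamma,
                 bg_level = bg_level, bleach_tau = bleach_tau, noise = noise,
                 dt = dt, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic imaging fixture
#'
#' Renders the fixture described by a [fixture_spec()]: paired on/off image
#' stacks for the donor (`s_dd`) and acceptor (`s_da`) channels, a labelled
#' ROI mask, a background mask, and the planted ground-truth table.  Output
#' is deterministic for a given spec (seeded noise).  When `dir` is given,
#' the stacks and masks are additionally written as multi-page / 16-bit
#' TIFF files plus a ground-truth CSV.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return List with `stacks` (named list of `rows x cols x n_t` arrays
#'   `dd_on, da_on, dd_off, da_off`), `rois` (integer label matrix),
#'   `background` (logical matrix), `truth` (data frame `cell, t_index,
#'   time_s, theta1, theta2`), `time` (cycle times) and `spec`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  nr <- spec$dim[1]; nc <- spec$dim[2]
  n_cells <- nrow(spec$cells)
  n_t <- if (n_cells) ncol(spec$theta1) else 0L

  rois <- matrix(0L, nr, nc)
  if (n_cells) {
    rr <- row(rois); cc <- col(rois)
    for (i in seq_len(n_cells)) {
      inside <- (rr - spec$cells$row[i])^2 + (cc - spec$cells$col[i])^2 <=
        spec$cells$radius[i]^2
      rois[inside] <- i
    }
  }
  background <- rois == 0L

  mk_stack <- function() array(0, c(nr, nc, n_t))
  stacks <- list(dd_on = mk_stack(), da_on = mk_stack(),
                 dd_off = mk_stack(), da_off = mk_stack())
  time <- if (n_t) (seq_len(n_t) - 1L) * spec$dt else numeric(0)

  for (k in seq_len(n_t)) {
    bleach <- if (is.finite(spec$bleach_tau)) exp(-time[k] / spec$bleach_tau) else 1
    n_eff <- spec$brightness * bleach
    frame <- list(dd_on = matrix(spec$bg_level, nr, nc),
                  da_on = matrix(spec$bg_level, nr, nc),
                  dd_off = matrix(spec$bg_level, nr, nc),
                  da_off = matrix(spec$bg_level, nr, nc))
    for (i in seq_len(n_cells)) {
      th <- c(spec$theta1[i, k], spec$theta2[i, k])
      rho <- spec$rho0^(1 - th)
      dd_on <- sum(n_eff * (1 - th))
      da_on <- sum(spec$gamma * n_eff * th)
      dd_off <- sum(rho * n_eff * (1 - th))
      da_off <- sum(rho * spec$gamma * n_eff * th)
      mask <- rois == i
      frame$dd_on[mask] <- frame$dd_on[mask] + dd_on
      frame$da_on[mask] <- frame$da_on[mask] + da_on
      frame$dd_off[mask] <- frame$dd_off[mask] + dd_off
      frame$da_off[mask] <- frame$da_off[mask] + da_off
    }
    for (ch in names(stacks)) stacks[[ch]][, , k] <- frame[[ch]]
  }

  if (spec$noise == "poisson" && n_t) {
    stacks <- withr::with_seed(spec$seed, lapply(stacks, function(a) {
      array(rpois(length(a), a), dim(a))
    }))
  }

  truth <- if (n_cells && n_t) {
    data.frame(cell = rep(seq_len(n_cells), each = n_t),
               t_index = rep(seq_len(n_t), n_cells),
               time_s = rep(time, n_cells),
               theta1 = as.vector(t(spec$theta1)),
               theta2 = as.vector(t(spec$theta2)))
  } else {
    data.frame(cell = integer(0), t_index = integer(0), time_s = numeric(0),
               theta1 = numeric(0), theta2 = numeric(0))
  }

  out <- list(stacks = stacks, rois = rois, background = background,
              truth = truth, time = time, spec = spec)
  if (!is.null(dir)) .write_fixture(out, dir)
  out
}

# TIFF/CSV serialisation of a fixture.  Stacks are written as 32-bit float
# multi-page TIFFs scaled to [0, 1] by a per-stack factor recorded in
# scale.csv; the ROI mask as 16-bit TIFF.
.write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- vapply(fx$stacks, function(a) max(a, 1), numeric(1))
  for (ch in names(fx$stacks)) {
    a <- fx$stacks[[ch]]
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scales[[ch]])
    if (length(pages)) {
      tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                      bits.per.sample = 32L)
    }
  }
  tiff::writeTIFF(fx$rois / 65535, file.path(dir, "rois.tif"),
                  bits.per.sample = 16L)
  write.csv(data.frame(channel = names(scales), scale = unname(scales)),
            file.path(dir, "scale.csv"), row.names = FALSE)
  write.csv(fx$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a fixture written by [generate_fixture()]
#'
#' @param dir Directory holding the TIFF stacks, masks and truth table.
#' @return List with the same `stacks`, `rois`, `background`, `truth` and
#'   `time` elements as [generate_fixture()] returns.
#' @export
read_fixture <- function(dir) {
  scales <- read.csv(file.path(dir, "scale.csv"), stringsAsFactors = FALSE)
  stacks <- list()
  for (ch in scales$channel) {
    f <- file.path(dir, paste0(ch, ".tif"))
    sc <- scales$scale[scales$channel == ch]
    if (file.exists(f)) {
      pages <- tiff::readTIFF(f, all = TRUE)
      stacks[[ch]] <- simplify2array(pages) * sc
    }
  }
  rois <- round(tiff::readTIFF(file.path(dir, "rois.tif")) * 65535)
  truth <- read.csv(file.path(dir, "truth.csv"))
  list(stacks = stacks, rois = matrix(as.integer(rois), nrow(rois)),
       background = rois == 0, truth = truth,
       time = sort(unique(truth$time_s)))
}

#' Assemble per-cell acquisition traces from a fixture
#'
#' Runs [extract_roi_traces()] on all four channel stacks of a fixture and
#' interleaves them into the alternating on/off trace tables consumed by
#' [unmix_timeseries()] (off acquisitions are timestamped 1 s after the
#' corresponding on acquisition).
#'
#' @param fx A fixture as returned by [generate_fixture()] or
#'   [read_fixture()].
#' @return Named list of data frames (one per ROI) with columns
#'   `time_s, state, s_dd, s_da, s_aa`.
#' @export
fixture_traces <- function(fx) {
  time <- fx$time
  tr <- lapply(fx$stacks, function(stack)
    extract_roi_traces(stack, fx$rois, fx$background, time = time))
  labels <- names(tr$dd_on)
  out <- lapply(labels, function(lab) {
    n_t <- length(time)
    df <- data.frame(
      time_s = as.vector(rbind(time, time + 1)),
      state = rep(c("on", "off"), n_t),
      s_dd = as.vector(rbind(tr$dd_on[[lab]]$value, tr$dd_off[[lab]]$value)),
      s_da = as.vector(rbind(tr$da_on[[lab]]$value, tr$da_off[[lab]]$value)),
      s_aa = NA_real_, stringsAsFactors = FALSE)
    df
  })
  names(out) <- labels
  out
}
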