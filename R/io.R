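#' Read a per-ROI acquisition trace table
#'
#' Trace CSVs hold one row per fluorescence acquisition with columns
#' `time_s, state, s_dd, s_da, s_aa` (UTF-8, comma separated, `.` decimal).
#' `s_aa` cells may be blank: the directly excited acceptor channel is
#' measured at a reduced cadence, and blank cells are read as `NA` (absent),
#' never as zero.
#'
#' @param path CSV file path.
#' @return Data frame with the five columns (`s_aa` may contain `NA`).
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "state", "s_dd", "s_da")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_pcfret(paste0("'", path, "' is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "pcfret_parse_error")
  }
  if (!"s_aa" %in% names(df)) df$s_aa <- NA_real_
  for (col in c("time_s", "s_dd", "s_da", "s_aa")) {
    v <- df[[col]]
    if (is.character(v)) v[v == ""] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) & !(is.na(df[[col]]) | df[[col]] == "") & col != "s_aa")
    if (length(bad)) {
      stop_pcfret(sprintf("'%s' row %d: non-numeric value in column '%s'",
                          path, bad[1], col), "pcfret_parse_error")
    }
    df[[col]] <- v
  }
  if (!all(df$state %in% c("on", "off"))) {
    stop_pcfret(sprintf("'%s': column 'state' must be 'on' or 'off'", path),
                "pcfret_parse_error")
  }
  df[c("time_s", "state", "s_dd", "s_da", "s_aa")]
}

#' Write a per-ROI acquisition trace table
#'
#' Inverse of [read_trace_csv()]; `NA` values of `s_aa` are written as blank
#' cells so that a write/read round trip is lossless.
#'
#' @param trace Data frame with columns `time_s, state, s_dd, s_da, s_aa`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  required <- c("time_s", "state", "s_dd", "s_da")
  missing_cols <- setdiff(required, names(trace))
  if (length(missing_cols)) {
    stop_pcfret(paste("trace is missing column(s):",
                      paste(missing_cols, collapse = ", ")),
                "pcfret_parse_error")
  }
  if (!"s_aa" %in% names(trace)) trace$s_aa <- NA_real_
  write.csv(trace[c("time_s", "state", "s_dd", "s_da", "s_aa")], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Read a calibration measurement table
#'
#' Calibration tables hold pooled per-cell measurements of photoswitching
#' ratio versus the FRET metric: columns `theta, rho, channel, pair_id`.
#'
#' @param path CSV file path.
#' @return Data frame with the four columns.
#' @export
read_calibration_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("theta", "rho", "channel", "pair_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_pcfret(paste0("'", path, "' is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "pcfret_parse_error")
  }
  df[required]
}

#' Serialize calibration models to JSON
#'
#' @param models A [calibration_model()] or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(models, path) {
  if (inherits(models, "calibration_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(kind = m$kind, params = as.list(m$params), channel = m$channel,
         valid_range = m$valid_range, abscissa = m$abscissa,
         residual_norm = m$residual_norm)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read calibration models from JSON
#'
#' @param path JSON file written by [write_calibration()].
#' @return List of [calibration_model()] objects.
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(m) {
    calibration_model(kind = m$kind, params = unlist(m$params),
                      channel = m$channel,
                      valid_range = unlist(m$valid_range),
                      abscissa = m$abscissa,
                      residual_norm = m$residual_norm %||% NA_real_)
  })
}

#' Serialize pair models to JSON
#'
#' @param pairs A [pair_model()] or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pair_models <- function(pairs, path) {
  if (inherits(pairs, "pair_model")) pairs <- list(pairs)
  ser_cal <- function(m) {
    if (is.null(m)) return(NULL)
    list(kind = m$kind, params = as.list(m$params), channel = m$channel,
         valid_range = m$valid_range, abscissa = m$abscissa)
  }
  payload <- lapply(pairs, function(p) {
    list(pair_id = p$pair_id, gamma = p$gamma,
         donor = ser_cal(p$donor_cal), acceptor = ser_cal(p$acceptor_cal))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read pair models from JSON
#'
#' @param path JSON file written by [write_pair_models()].
#' @return List of [pair_model()] objects.
#' @export
read_pair_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_cal <- function(m) {
    if (is.null(m)) return(NULL)
    calibration_model(kind = m$kind, params = unlist(m$params),
                      channel = m$channel,
                      valid_range = unlist(m$valid_range),
                      abscissa = m$abscissa)
  }
  lapply(payload, function(p) {
    pair_model(p$pair_id, de_cal(p$donor), de_cal(p$acceptor),
               gamma = p$gamma)
  })
}

# Allowed run-config schema (top-level key -> allowed subkeys, NULL = free)
.config_schema <- list(
  correction = c("alpha", "delta", "gamma"),
  calibrations = NULL,
  scheme = c("channel_order", "on_label", "off_label", "saa_cadence"),
  study = NULL,
  fixture = NULL,
  analysis = NULL,
  intervals = NULL,
  stimulations = NULL,
  seed = NULL,
  output = NULL
)

#' Read and validate a run configuration
#'
#' Run configurations are YAML files holding correction factors, calibration
#' file references, the measurement-scheme description, simulation study
#' grids, stimulation intervals, seeds and output paths.  Unknown keys are
#' rejected to catch typos; the seed must be explicit when present.
#'
#' @param path YAML file path.
#' @return Named list with the validated configuration.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    stop_pcfret(sprintf("'%s' is not a YAML mapping", path),
                "pcfret_parse_error")
  }
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown)) {
    stop_pcfret(paste0("'", path, "': unknown config key(s): ",
                       paste(unknown, collapse = ", ")),
                "pcfret_parse_error")
  }
  for (key in names(cfg)) {
    allowed <- .config_schema[[key]]
    if (!is.null(allowed) && is.list(cfg[[key]])) {
      bad <- setdiff(names(cfg[[key]]), allowed)
      if (length(bad)) {
        stop_pcfret(paste0("'", path, "': unknown key(s) under '", key, "': ",
                           paste(bad, collapse = ", ")),
                    "pcfret_parse_error")
      }
    }
  }
  if (!is.null(cfg$correction)) {
    cfg$correction <- do.call(correction_factors, cfg$correction)
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
      stop_pcfret("config 'seed' must be an integer", "pcfret_parse_error")
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  cfg
}
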