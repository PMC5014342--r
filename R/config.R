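#' Default configuration
#'
#' Nested list of every tunable the pipelines expose.  Values the source
#' study leaves open (FSR thresholds, Savitzky-Golay parameters, the risk
#' proportionality constant, ...) live here so an analysis is fully
#' declarative: load a YAML file with [load_config()] and pass the result to
#' the pipeline functions.
#'
#' Keys:
#' \describe{
#'   \item{strike}{`onset_frac` (0.3) / `release_frac` (0.1): hysteresis
#'     fractions of the per-recording FSR maximum that open/close a
#'     heel-strike window; `sg_order` (3) / `sg_window` (11): Savitzky-Golay
#'     polynomial order and odd window length in samples; `max_window_ms`
#'     (250): cap on the strike window so it covers the impact transient.}
#'   \item{soil}{`centroid_method` ("area"): spectral-centroid convention;
#'     `exclusion_x` (50 Hz) / `exclusion_y` (8e-4): outlier rectangle used
#'     when a model is built without training data; `fit_exclusion` (TRUE):
#'     calibrate the rectangle from training centroids instead;
#'     `n_restarts` (20) and `sparsity` (0.05): weight-optimisation
#'     restarts and the post-fit threshold below which weights are zeroed.}
#'   \item{gait}{`min_step_interval_s` (0.3) and `prominence_frac` (0.5):
#'     step-peak picking; `lowpass_hz` (10): low-pass corner for the
#'     acceleration magnitude; `turn_factor` (1.3): step-interval multiple
#'     that marks the turning phase; `stand_thresh_frac` (0.5),
#'     `sustain_s` (0.5), `gap_merge_s` (0.7): load-threshold logic framing
#'     the trial.}
#'   \item{risk}{`alpha_c` (1): proportionality constant of the
#'     speed-inverse weighting in the risk index.}
#'   \item{cue}{`above_frac` (0.10): cue frequency relative to baseline
#'     cadence; `pulse_ms` (50): pulse duration.}
#'   \item{io}{`accel_in_g` (FALSE): interpret stored acceleration as g and
#'     convert to m/s^2 on read.}
#'   \item{seed}{integer seed for every stochastic step.}
#' }
#'
#' @return Nested named list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$strike$onset_frac
default_config <- function() {
  list(
    strike = list(
      onset_frac = 0.3,
      release_frac = 0.1,
      sg_order = 3L,
      sg_window = 11L,
      max_window_ms = 250
    ),
    soil = list(
      centroid_method = "area",
      exclusion_x = 50,
      exclusion_y = 8e-4,
      fit_exclusion = TRUE,
      n_restarts = 20L,
      sparsity = 0.05
    ),
    gait = list(
      min_step_interval_s = 0.3,
      prominence_frac = 0.5,
      lowpass_hz = 10,
      turn_factor = 1.3,
      stand_thresh_frac = 0.5,
      sustain_s = 0.5,
      gap_merge_s = 0.7
    ),
    risk = list(alpha_c = 1),
    cue = list(above_frac = 0.10, pulse_ms = 50),
    io = list(accel_in_g = FALSE),
    seed = 1L
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it over [default_config()].  Keys not
#' present in the defaults are rejected, so typos fail loudly instead of
#' silently running with defaults.
#'
#' @param path Path to a YAML file (may set any subset of keys).
#' @param defaults Base configuration to merge into.
#' @return Nested named list with the same shape as [default_config()].
#' @export
load_config <- function(path, defaults = default_config()) {
  if (!file.exists(path)) {
    stop_solegait(paste0("config file not found: ", path), "config")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) {
    return(defaults)
  }
  merge_config(defaults, user, parent = character())
}

merge_config <- function(base, user, parent) {
  if (!is.list(user)) {
    stop_solegait(
      paste0("config section '", paste(parent, collapse = "."), "' must be a mapping"),
      "config"
    )
  }
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop_solegait(
      paste0(
        "unknown config key(s): ",
        paste(paste(c(parent, ""), collapse = "."), unknown, sep = "", collapse = ", ")
      ),
      "config"
    )
  }
  for (key in names(user)) {
    if (is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], parent = c(parent, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}
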