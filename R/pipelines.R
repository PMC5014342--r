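#' End-to-end soil-differentiation pipeline
#'
#' From labelled recordings to a fitted model and its detection rate:
#' detects heel strikes, runs the preprocessing chain, extracts the
#' spectral-centroid and time-domain features, fits the weighted-level
#' model and evaluates it.
#'
#' @param dataset Either a tibble with `soil` and `recording` columns
#'   (e.g. from [simulate_soil_dataset()]) or a directory of recording
#'   files whose metadata carries a `soil` label.
#' @param config Configuration list, see [default_config()].
#' @param feature_cols Feature subset to weight (default: all six).
#' @return A `soil_report` list: `model`, `features` (per-strike tibble),
#'   `detection_rate`, `n_strikes`, `config`.
#' @export
run_soil_pipeline <- function(dataset, config = default_config(),
                              feature_cols = SOIL_FEATURES) {
  if (is.character(dataset)) {
    dataset <- read_soil_dir(dataset, config)
  }
  if (!is.data.frame(dataset) || nrow(dataset) == 0) {
    stop_solegait("no labelled recordings to process", "parameter")
  }
  rates <- unique(purrr::map_dbl(dataset$recording, sample_rate))
  if (length(rates) != 1) {
    stop_solegait("recordings have mixed sample rates; resample first", "parameter")
  }
  strikes <- dataset_strikes(
    dataset,
    onset_frac = config$strike$onset_frac,
    release_frac = config$strike$release_frac,
    max_window_ms = config$strike$max_window_ms
  )
  if (nrow(strikes) == 0) {
    stop_solegait("no heel strikes detected in the dataset", "segmentation")
  }
  features <- strike_features(
    strikes, rates,
    sg_order = config$strike$sg_order,
    sg_window = config$strike$sg_window,
    centroid_method = config$soil$centroid_method
  )
  model <- fit_soil_model(
    features,
    feature_cols = feature_cols,
    seed = config$seed,
    n_restarts = config$soil$n_restarts,
    sparsity = config$soil$sparsity,
    exclusion = if (isTRUE(config$soil$fit_exclusion)) {
      NULL
    } else {
      c(config$soil$exclusion_x, config$soil$exclusion_y)
    }
  )
  structure(
    list(
      model = model,
      features = features,
      detection_rate = detection_rate(features, model),
      n_strikes = nrow(features),
      config = config
    ),
    class = "soil_report"
  )
}

read_soil_dir <- function(dir, config) {
  paths <- list.files(dir, pattern = "\\.(csv|jsonl)$", full.names = TRUE)
  if (length(paths) == 0) {
    stop_solegait(paste0("no recordings (*.csv, *.jsonl) in ", dir), "io")
  }
  recs <- purrr::map(paths, read_recording, accel_in_g = config$io$accel_in_g)
  tibble::tibble(
    soil = purrr::map_chr(recs, function(r) {
      as.character(recording_meta(r)$soil %||% NA_character_)
    }),
    recording = recs
  )
}

#' @export
print.soil_report <- function(x, ...) {
  cat("<soil_report>", x$n_strikes, "strikes,",
    length(x$model$classes), "classes\n")
  cat("  detection rate:", format(x$detection_rate, digits = 4), "\n")
  print(x$model)
  invisible(x)
}

#' End-to-end TUG scoring pipeline
#'
#' Scores one TUG trial against baseline (reference-surface) trials:
#' segments the phases, detects steps, derives gait parameters and the
#' risk-of-falling index, categorizes the TUG time, and builds the
#' vibrotactile cue schedule at 10% above the baseline cadence together
#' with the activation decision.
#'
#' @param rec The TUG trial [recording()].
#' @param baselines List of at least two baseline [recording()]s (walking
#'   on the reference surface).
#' @param config Configuration list, see [default_config()].
#' @return A `tug_report` list: `phases`, `steps`, `gait`, `risk`,
#'   `category`, `baseline` (cadence, reference risk), `cue`
#'   (frequency, activation, schedule).
#' @export
run_tug_pipeline <- function(rec, baselines, config = default_config()) {
  if (!is.list(baselines) || length(baselines) < 2) {
    stop_solegait("need at least 2 baseline trials", "insufficient_baseline")
  }
  score_one <- function(r) {
    phases <- segment_tug(
      r,
      stand_thresh_frac = config$gait$stand_thresh_frac,
      sustain_s = config$gait$sustain_s,
      gap_merge_s = config$gait$gap_merge_s,
      turn_factor = config$gait$turn_factor,
      min_step_interval_s = config$gait$min_step_interval_s,
      prominence_frac = config$gait$prominence_frac,
      lowpass_hz = config$gait$lowpass_hz
    )
    steps <- detect_steps(
      r, phases,
      min_interval_s = config$gait$min_step_interval_s,
      prominence_frac = config$gait$prominence_frac,
      lowpass_hz = config$gait$lowpass_hz
    )
    gait <- gait_params(steps, r, phases)
    list(
      phases = phases, steps = steps, gait = gait,
      risk = risk_of_falling(gait, alpha_c = config$risk$alpha_c)
    )
  }

  base_scores <- purrr::map(baselines, score_one)
  base_gait <- dplyr::bind_rows(purrr::map(base_scores, "gait"))
  baseline_cad <- baseline_cadence(base_gait)
  reference_risk <- mean(purrr::map_dbl(base_scores, function(s) s$risk$risk))

  trial <- score_one(rec)
  freq <- cue_frequency(baseline_cad, above_frac = config$cue$above_frac)
  activate <- should_cue(trial$risk$risk, reference_risk)
  schedule <- generate_schedule(
    freq,
    duration = trial$phases$tug_time,
    pulse_ms = config$cue$pulse_ms
  )

  structure(
    list(
      phases = trial$phases,
      steps = trial$steps,
      gait = trial$gait,
      risk = trial$risk,
      category = categorize_tug(trial$phases),
      baseline = list(cadence = baseline_cad, reference_risk = reference_risk),
      cue = list(frequency = freq, activate = activate, schedule = schedule)
    ),
    class = "tug_report"
  )
}

#' @export
print.tug_report <- function(x, ...) {
  cat("<tug_report>\n")
  cat(sprintf(
    "  TUG time %.2f s (%s); %d steps, cadence %.1f steps/min, speed %.2f m/s\n",
    x$phases$tug_time, x$category, x$gait$n_steps, x$gait$cadence_mean, x$gait$speed
  ))
  cat(sprintf(
    "  risk %.1f%% (CV_cad %.1f%%, CV_SL %.1f%%, alpha %.2f); reference %.1f%%\n",
    x$risk$risk, x$risk$cv_cadence, x$risk$cv_stride, x$risk$alpha,
    x$baseline$reference_risk
  ))
  cat(sprintf(
    "  cue: %s at %.1f pulses/min\n",
    if (x$cue$activate) "ACTIVE" else "off", x$cue$frequency
  ))
  invisible(x)
}

#' Serialize a TUG report to JSON
#'
#' @param report A `tug_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
tug_report_json <- function(report, path = NULL) {
  payload <- list(
    phases = as.list(report$phases[1, ]),
    steps = report$steps$time,
    step_source = report$steps$source[1],
    gait = list(
      n_steps = report$gait$n_steps,
      cadence_mean = report$gait$cadence_mean,
      speed = report$gait$speed,
      inst_cadence = report$gait$inst_cadence[[1]],
      stride_lengths = report$gait$stride_lengths[[1]]
    ),
    risk = as.list(report$risk[1, ]),
    category = report$category,
    baseline = report$baseline,
    cue = list(
      frequency = report$cue$frequency,
      activate = report$cue$activate,
      pulse_onsets = report$cue$schedule$onset,
      pulse_duration = report$cue$schedule$duration[1]
    )
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
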