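#' Segment a TUG trial into its phases
#'
#' Frames the trial with the summed FSR load: the test starts at the first
#' sustained rise of total force above a standing-load threshold (default
#' half the median loaded value, sustained at least `sustain_s`) and ends
#' when the force falls back below it for good.  Short unloaded gaps (the
#' swing phases between steps) are merged before the sustained-run logic so
#' the loaded period is contiguous.  Step peaks inside the loaded period
#' then anchor the walking phases: the sit-to-stand phase ends at the first
#' step, the walk back ends at the last step, and the turning phase is the
#' contiguous run of step intervals exceeding `turn_factor` times the
#' median interval that lies nearest the temporal midpoint of the walk
#' (turning slows stepping on the 3 m out-and-back course).
#'
#' @param rec A [recording()] holding one full TUG trial with unloaded
#'   sitting at both ends.
#' @param stand_thresh_frac Threshold as a fraction of the median loaded
#'   FSR value.
#' @param sustain_s Minimum duration (s) a crossing must hold.
#' @param gap_merge_s Unloaded gaps shorter than this (s) are bridged.
#' @param turn_factor Step-interval multiple flagging the turn.
#' @param min_step_interval_s,prominence_frac,lowpass_hz Step-peak
#'   picking, see [detect_steps()].
#' @return One-row `tug_phases` tibble: `t_start`, `t_stand_end`,
#'   `t_turn_start`, `t_turn_end`, `t_walkback_end`, `t_end`, `tug_time`
#'   (all seconds).
#' @export
segment_tug <- function(rec, stand_thresh_frac = 0.5, sustain_s = 0.5,
                        gap_merge_s = 0.7, turn_factor = 1.3,
                        min_step_interval_s = 0.3, prominence_frac = 0.5,
                        lowpass_hz = 10) {
  validate_recording(rec)
  rate <- sample_rate(rec)
  f <- rowSums(as.matrix(tibble::as_tibble(unclass(rec))[fsr_channels(rec)]))
  peak <- max(f)
  if (!is.finite(peak) || peak <= 0) {
    stop_solegait("no FSR load anywhere in the recording", "segmentation")
  }
  loaded <- f[f > 0.5 * peak]
  thr <- stand_thresh_frac * median(loaded)
  above <- f > thr
  above <- merge_short_gaps(above, max(1L, round(gap_merge_s * rate)))
  runs <- logical_runs(above)
  runs <- runs[runs$value & (runs$end - runs$start + 1) >= sustain_s * rate, , drop = FALSE]
  if (nrow(runs) == 0) {
    stop_solegait(
      "no sustained load plateau: is a full sit-stand-walk-sit trial present?",
      "segmentation"
    )
  }
  t_start <- rec$t[runs$start[1]]
  t_end <- rec$t[runs$end[nrow(runs)]]

  in_trial <- rec$t >= t_start & rec$t <= t_end
  steps <- step_peak_times(
    rec$t[in_trial], accel_magnitude(rec)[in_trial], rate,
    min_step_interval_s, prominence_frac, lowpass_hz
  )
  if (length(steps) < 2) {
    stop_solegait("fewer than 2 step peaks inside the loaded period", "segmentation")
  }
  t_stand_end <- steps[1]
  t_walkback_end <- steps[length(steps)]

  turn <- locate_turn(steps, turn_factor)

  phases <- tibble::tibble(
    t_start = t_start,
    t_stand_end = t_stand_end,
    t_turn_start = turn[1],
    t_turn_end = turn[2],
    t_walkback_end = t_walkback_end,
    t_end = t_end,
    tug_time = t_end - t_start
  )
  class(phases) <- c("tug_phases", class(phases))
  phases
}

# Contiguous run of intervals > turn_factor * median, nearest the temporal
# midpoint of the walk; falls back to the single longest interval.
locate_turn <- function(steps, turn_factor) {
  iv <- diff(steps)
  slow <- iv > turn_factor * median(iv)
  if (!any(slow)) {
    k <- which.max(iv)
    return(c(steps[k], steps[k + 1]))
  }
  runs <- logical_runs(slow)
  runs <- runs[runs$value, , drop = FALSE]
  mid <- (steps[1] + steps[length(steps)]) / 2
  centers <- (steps[runs$start] + steps[runs$end + 1]) / 2
  k <- which.min(abs(centers - mid))
  c(steps[runs$start[k]], steps[runs$end[k] + 1])
}

merge_short_gaps <- function(above, max_gap) {
  runs <- logical_runs(above)
  for (i in seq_len(nrow(runs))) {
    if (!runs$value[i] && i > 1 && i < nrow(runs) &&
        (runs$end[i] - runs$start[i] + 1) < max_gap) {
      above[runs$start[i]:runs$end[i]] <- TRUE
    }
  }
  above
}

logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  tibble::tibble(value = r$values, start = ends - r$lengths + 1, end = ends)
}

accel_magnitude <- function(rec) {
  ch <- accel_channels(rec)
  sqrt(rowSums(as.matrix(tibble::as_tibble(unclass(rec))[ch])^2))
}

step_peak_times <- function(tvec, mag, rate, min_interval_s, prominence_frac,
                            lowpass_hz) {
  x <- mag - mean(mag)
  if (length(x) > 12 && lowpass_hz < rate / 2) {
    bf <- signal::butter(2, lowpass_hz / (rate / 2))
    x <- signal::filtfilt(bf, x)
  }
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    return(numeric(0))
  }
  pk <- pracma::findpeaks(x,
    minpeakheight = prominence_frac * s,
    minpeakdistance = max(1L, round(min_interval_s * rate))
  )
  if (is.null(pk)) numeric(0) else sort(tvec[pk[, 2]])
}

#' Detect step events in the walking portion of a TUG trial
#'
#' Steps are peaks of the acceleration magnitude (mean-removed, low-pass
#' filtered at `lowpass_hz`) between the end of sit-to-stand and the last
#' step, with a minimum separation and a minimum height of
#' `prominence_frac` times the signal standard deviation.  The count is
#' validated against the FSR burst count over the same span; if they
#' disagree by more than 20% of the FSR count, the FSR burst peaks are
#' used instead (`source = "fsr"`) and a warning is raised.
#'
#' @param rec A [recording()].
#' @param phases A `tug_phases` row from [segment_tug()].
#' @param min_interval_s Minimum step separation in seconds.
#' @param prominence_frac Peak height threshold as a fraction of the
#'   signal standard deviation.
#' @param lowpass_hz Low-pass corner frequency in Hz.
#' @return Tibble `step_events`: `step`, `time` (s), `source`
#'   (`"accel"` or `"fsr"`).
#' @export
detect_steps <- function(rec, phases, min_interval_s = 0.3,
                         prominence_frac = 0.5, lowpass_hz = 10) {
  validate_recording(rec)
  rate <- sample_rate(rec)
  eps <- 0.5 / rate
  # Search a margin beyond the walking portion so peaks sitting exactly on
  # its boundaries (the first and last steps) are visible to the peak
  # finder, then keep only peaks inside the portion.
  margin <- min_interval_s
  span <- rec$t >= phases$t_stand_end - margin & rec$t <= phases$t_walkback_end + margin
  times <- step_peak_times(
    rec$t[span], accel_magnitude(rec)[span], rate,
    min_interval_s, prominence_frac, lowpass_hz
  )
  times <- times[times >= phases$t_stand_end - eps & times <= phases$t_walkback_end + eps]
  f <- rowSums(as.matrix(tibble::as_tibble(unclass(rec))[fsr_channels(rec)]))[span]
  bursts <- hysteresis_windows(f, 0.3 * max(f), 0.1 * max(f))
  n_fsr <- nrow(bursts)
  source <- "accel"
  if (n_fsr > 0 && abs(length(times) - n_fsr) > 0.2 * n_fsr) {
    warn_solegait(
      sprintf(
        "accelerometer step count (%d) disagrees with FSR burst count (%d); using FSR",
        length(times), n_fsr
      ),
      "step_source"
    )
    tspan <- rec$t[span]
    times <- purrr::map2_dbl(bursts$start, bursts$end, function(a, b) {
      seg <- a:(min(b, length(f)) - if (b > length(f)) 0 else 1)
      tspan[seg[which.max(f[seg])]]
    })
    times <- sort(times)
    source <- "fsr"
  }
  if (length(times) < 2) {
    stop_solegait("fewer than 2 steps detected", "insufficient_steps")
  }
  out <- tibble::tibble(step = seq_along(times), time = times, source = source)
  class(out) <- c("step_events", class(out))
  out
}

#' Stride length from per-stride acceleration
#'
#' `SL = 0.98 * (sum(|a_i|) / N)^(1/3)` with `a_i` the mean-removed,
#' rectified acceleration samples of the stride and `N` the sample count.
#' Rectification is needed because the signed mean of oscillatory gait
#' acceleration is near zero.
#'
#' @param accel_segment Numeric vector of acceleration samples (m/s^2)
#'   covering one stride.
#' @return Stride length in metres.
#' @export
#' @examples
#' stride_length(rep(c(1, -1), 50))  # 0.98
stride_length <- function(accel_segment) {
  if (length(accel_segment) == 0) {
    stop_solegait("empty stride segment", "parameter")
  }
  a <- abs(accel_segment - mean(accel_segment))
  0.98 * (sum(a) / length(a))^(1 / 3)
}

#' Gait parameters from step events
#'
#' Instantaneous cadence is `60 / step interval` (steps/min); intervals
#' falling inside the turning phase are excluded from the cadence and
#' stride statistics so the deliberate slow-down of the turn does not
#' masquerade as gait variability.  Strides pair consecutive steps within
#' each straight-walking run (the same-foot approximation with one
#' instrumented side); each stride's length comes from [stride_length()]
#' on the vertical acceleration between its bounding steps.  Walking speed
#' is the accumulated stride length divided by the walking-portion
#' duration (turn included).
#'
#' @param steps A `step_events` tibble from [detect_steps()].
#' @param rec The [recording()].
#' @param phases The `tug_phases` row.
#' @return One-row `gait_params` tibble: `n_steps`, `cadence_mean`
#'   (steps/min), `speed` (m/s), plus list columns `inst_cadence` and
#'   `stride_lengths`.
#' @export
gait_params <- function(steps, rec, phases) {
  if (nrow(steps) < 3) {
    stop_solegait("need at least 3 steps for gait parameters", "insufficient_steps")
  }
  times <- steps$time
  # Boundary steps (at the turn start/end) belong to the straight runs;
  # only the steps strictly inside the turn are excluded from strides.
  in_turn <- times > phases$t_turn_start + 1e-9 & times < phases$t_turn_end - 1e-9
  iv_start <- head(times, -1)
  iv_end <- tail(times, -1)
  iv_in_turn <- iv_start >= phases$t_turn_start - 1e-9 &
    iv_end <= phases$t_turn_end + 1e-9
  walk_iv <- (iv_end - iv_start)[!iv_in_turn]
  if (length(walk_iv) < 2) {
    stop_solegait("too few walking step intervals outside the turn", "insufficient_steps")
  }
  inst_cadence <- 60 / walk_iv

  # Strides: pair consecutive steps within each straight-walk run.
  run_id <- cumsum(c(TRUE, diff(in_turn) != 0))
  strides <- list()
  for (rid in unique(run_id[!in_turn])) {
    st <- times[run_id == rid & !in_turn]
    m <- length(st)
    if (m >= 3) {
      bounds <- st[seq(1, m, by = 2)]
      for (j in seq_len(length(bounds) - 1)) {
        strides[[length(strides) + 1]] <- c(bounds[j], bounds[j + 1])
      }
    }
  }
  if (length(strides) == 0) {
    stop_solegait("no complete stride outside the turn", "insufficient_steps")
  }
  rate <- sample_rate(rec)
  sl <- vapply(strides, function(b) {
    i0 <- which.min(abs(rec$t - b[1]))
    i1 <- which.min(abs(rec$t - b[2]))
    stride_length(rec$accel_z[i0:(i1 - 1)])
  }, numeric(1))

  out <- tibble::tibble(
    n_steps = nrow(steps),
    cadence_mean = mean(inst_cadence),
    speed = sum(sl) / (phases$t_walkback_end - phases$t_stand_end),
    inst_cadence = list(inst_cadence),
    stride_lengths = list(sl)
  )
  class(out) <- c("gait_params", class(out))
  out
}

#' Coefficient of variation (percent)
#'
#' `CV = 100 * sd / mean` with the sample (n-1) standard deviation, the
#' gait-variability statistic of Gabell and Nayak.
#'
#' @param series Numeric vector, length at least 2, non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4, 6))  # 50
coefficient_of_variation <- function(series) {
  if (length(series) < 2) {
    stop_solegait("CV needs at least 2 values", "parameter")
  }
  m <- mean(series)
  if (abs(m) < 1e-12) {
    stop_solegait("CV undefined for a zero-mean series", "undefined")
  }
  100 * sd(series) / m
}

#' Risk-of-falling index from gait parameters
#'
#' `risk = alpha * (CV_cadence + CV_stride)` with
#' `alpha = alpha_c / speed` (the speed taken as a dimensionless value),
#' so irregular gait raises the risk and brisk walking lowers it.
#'
#' @param gp A `gait_params` row from [gait_params()].
#' @param alpha_c Proportionality constant of the inverse-speed weighting.
#' @return One-row `risk_score` tibble: `cv_cadence`, `cv_stride` (both
#'   percent), `alpha`, `speed`, `risk` (percent).
#' @export
risk_of_falling <- function(gp, alpha_c = 1) {
  if (!is.finite(gp$speed) || gp$speed <= 0) {
    stop_solegait("walking speed must be positive", "parameter")
  }
  cv_cad <- coefficient_of_variation(gp$inst_cadence[[1]])
  cv_sl <- coefficient_of_variation(gp$stride_lengths[[1]])
  alpha <- alpha_c / gp$speed
  out <- tibble::tibble(
    cv_cadence = cv_cad,
    cv_stride = cv_sl,
    alpha = alpha,
    speed = gp$speed,
    risk = alpha * (cv_cad + cv_sl)
  )
  class(out) <- c("risk_score", class(out))
  out
}

#' Mobility category from the TUG time
#'
#' Under 10 s is the mobility of independent adults (`"normal"`), over
#' 16 s is associated with an increased risk of falling in daily living
#' (`"increased_risk"`), anything between (boundaries included) is
#' `"intermediate"`.
#'
#' @param phases A `tug_phases` row (or anything with `tug_time`).
#' @return `"normal"`, `"intermediate"` or `"increased_risk"`.
#' @export
categorize_tug <- function(phases) {
  tt <- phases$tug_time
  if (!is.finite(tt) || tt <= 0) {
    stop_solegait("TUG time must be positive", "parameter")
  }
  if (tt < 10) "normal" else if (tt > 16) "increased_risk" else "intermediate"
}

#' Plot TUG segmentation over the sensor traces
#'
#' Total FSR and acceleration magnitude with the phase boundaries as
#' vertical lines and the detected steps as points.
#'
#' @param rec A [recording()].
#' @param phases A `tug_phases` row.
#' @param steps Optional `step_events` tibble.
#' @return A ggplot.
#' @export
plot_tug_segmentation <- function(rec, phases, steps = NULL) {
  df <- dplyr::bind_rows(
    tibble::tibble(
      t = rec$t, value = accel_magnitude(rec), channel = "acceleration magnitude"
    ),
    tibble::tibble(
      t = rec$t,
      value = rowSums(as.matrix(tibble::as_tibble(unclass(rec))[fsr_channels(rec)])),
      channel = "total FSR"
    )
  )
  marks <- as.numeric(phases[1, c(
    "t_start", "t_stand_end", "t_turn_start", "t_turn_end",
    "t_walkback_end", "t_end"
  )])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = marks, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL)
  if (!is.null(steps)) {
    p <- p + ggplot2::geom_vline(
      xintercept = steps$time, colour = "steelblue",
      alpha = 0.4, linewidth = 0.2
    )
  }
  p
}
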