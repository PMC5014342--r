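#' Baseline cadence from reference walking trials
#'
#' The preferred walking cadence is the mean of the per-trial mean
#' cadences from at least two reference trials recorded on the lowest-risk
#' surface (concrete).
#'
#' @param trials A `gait_params` tibble with one row per trial (stack
#'   single-trial results with [dplyr::bind_rows()]).
#' @return Baseline cadence in steps/min.
#' @export
baseline_cadence <- function(trials) {
  if (!is.data.frame(trials) || !"cadence_mean" %in% names(trials)) {
    stop_solegait("trials must be gait_params rows with cadence_mean", "parameter")
  }
  if (nrow(trials) < 2) {
    stop_solegait("baseline cadence needs at least 2 reference trials", "insufficient_baseline")
  }
  mean(trials$cadence_mean)
}

#' Cueing frequency at 10% above baseline
#'
#' Rhythmic cues are delivered slightly faster than the walker's preferred
#' cadence to entrain a brisker, more regular step.
#'
#' @param baseline Baseline cadence in steps/min (positive).
#' @param above_frac Fractional increase over baseline (default 0.10).
#' @return Cue frequency in pulses/min.
#' @export
#' @examples
#' cue_frequency(100)  # 110
cue_frequency <- function(baseline, above_frac = 0.10) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop_solegait("baseline cadence must be positive", "parameter")
  }
  (1 + above_frac) * baseline
}

#' Generate a rhythmic vibrotactile pulse schedule
#'
#' Pulses of `pulse_ms` milliseconds at uniform `60/frequency` spacing,
#' starting at t = 0 and ending strictly before `duration`.  This is the
#' data-level realization of the actuator's PWM rhythmic pattern; the
#' motor drive waveform itself is hardware.
#'
#' @param frequency Pulses per minute (positive).
#' @param duration Schedule duration in seconds (positive).
#' @param pulse_ms Pulse duration in milliseconds (default 50); must be
#'   shorter than the inter-pulse interval.
#' @return A `cue_schedule` tibble: `onset` (s), `duration` (s); the
#'   frequency travels as an attribute.
#' @export
#' @examples
#' generate_schedule(60, 3)  # pulses at 0, 1, 2 s
generate_schedule <- function(frequency, duration, pulse_ms = 50) {
  if (!is.finite(frequency) || frequency <= 0) {
    stop_solegait("frequency must be positive", "parameter")
  }
  if (!is.finite(duration) || duration <= 0) {
    stop_solegait("duration must be positive", "parameter")
  }
  interval <- 60 / frequency
  pulse_s <- pulse_ms / 1000
  if (pulse_s >= interval) {
    stop_solegait(
      sprintf(
        "pulse of %g ms would overlap the next pulse at %g pulses/min",
        pulse_ms, frequency
      ),
      "parameter"
    )
  }
  n <- floor((duration - 1e-12) / interval) + 1
  out <- tibble::tibble(
    onset = (seq_len(n) - 1) * interval,
    duration = pulse_s
  )
  attr(out, "frequency") <- frequency
  class(out) <- c("cue_schedule", class(out))
  out
}

#' Should the cue be activated?
#'
#' The actuator switches on when the current risk of falling strictly
#' exceeds the reference risk measured on the baseline surface.
#'
#' @param current_risk,reference_risk Risk-of-falling values in percent
#'   (non-negative).
#' @return Logical.
#' @export
#' @examples
#' should_cue(25, 18)  # TRUE
#' should_cue(18, 18)  # FALSE
should_cue <- function(current_risk, reference_risk) {
  if (!is.finite(current_risk) || !is.finite(reference_risk) ||
      current_risk < 0 || reference_risk < 0) {
    stop_solegait("risk values must be non-negative", "parameter")
  }
  current_risk > reference_risk
}

#' Plot a cue schedule as an on/off timeline
#'
#' @param object A `cue_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cue_schedule <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$onset, xmax = .data$onset + .data$duration,
        ymin = 0, ymax = 1
      ),
      fill = "steelblue"
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "time [s]", y = NULL,
      title = sprintf("%g pulses/min, %g ms pulses",
        attr(object, "frequency"), object$duration[1] * 1000
      )
    )
}
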