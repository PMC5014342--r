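#' Detect heel-strike windows from the heel FSR channel
#'
#' The heel FSR gates the impact: a window opens when the force rises above
#' `onset_frac` of the per-recording channel maximum and closes when it
#' falls below `release_frac` of that maximum (hysteresis, so in-burst
#' noise above the release level does not split a strike).  The vertical
#' acceleration between the crossings is extracted; a cap of
#' `max_window_ms` keeps the window on the impact transient.
#'
#' @param rec A [recording()].
#' @param onset_frac,release_frac Hysteresis fractions of the channel
#'   maximum, `0 < release_frac < onset_frac < 1`.
#' @param max_window_ms Cap on window duration in milliseconds.
#' @param channel FSR channel name; defaults to `fsr_heel` when present,
#'   otherwise the first `fsr_*` channel.
#' @return Tibble with one row per strike: `strike`, `start`, `end`
#'   (sample indices, half-open `[start, end)`), `soil` (label from the
#'   recording metadata, `NA` if none) and `signal` (list column of raw
#'   `accel_z` segments, m/s^2).  A flat or all-zero FSR channel yields
#'   zero rows.
#' @export
#' @examples
#' rec <- recording(
#'   data.frame(accel_z = c(0, 1, 2, 1, 0), fsr_heel = c(0, 8, 9, 8, 0)),
#'   sample_rate = 100
#' )
#' detect_strikes(rec)
detect_strikes <- function(rec, onset_frac = 0.3, release_frac = 0.1,
                           max_window_ms = 250, channel = NULL) {
  validate_recording(rec)
  if (!(release_frac > 0 && release_frac < onset_frac && onset_frac < 1)) {
    stop_solegait("need 0 < release_frac < onset_frac < 1", "parameter")
  }
  fsr <- fsr_channels(rec)
  channel <- channel %||% if ("fsr_heel" %in% fsr) "fsr_heel" else fsr[1]
  if (!channel %in% names(rec)) {
    stop_solegait(paste0("no such FSR channel: ", channel), "parameter")
  }
  f <- rec[[channel]]
  peak <- max(f)
  empty <- tibble::tibble(
    strike = integer(), start = integer(), end = integer(),
    soil = character(), signal = list()
  )
  if (!is.finite(peak) || peak <= 0) {
    return(empty)
  }
  bounds <- hysteresis_windows(f, onset_frac * peak, release_frac * peak)
  if (nrow(bounds) == 0) {
    return(empty)
  }
  cap <- max(1L, as.integer(round(max_window_ms / 1000 * sample_rate(rec))))
  bounds$end <- pmin(bounds$end, bounds$start + cap)
  soil <- recording_meta(rec)$soil %||% NA_character_
  tibble::tibble(
    strike = seq_len(nrow(bounds)),
    start = bounds$start,
    end = bounds$end,
    soil = as.character(soil),
    signal = purrr::map2(bounds$start, bounds$end, function(a, b) rec$accel_z[a:(b - 1)])
  )
}

# Hysteresis threshold crossings: returns half-open [start, end) windows in
# 1-based sample indices.  A window still open at the end of the trace is
# closed at n + 1.
hysteresis_windows <- function(x, on, off) {
  n <- length(x)
  starts <- integer(0)
  ends <- integer(0)
  open <- FALSE
  start <- 0L
  for (i in seq_len(n)) {
    if (!open && x[i] >= on) {
      open <- TRUE
      start <- i
    } else if (open && x[i] < off) {
      open <- FALSE
      starts <- c(starts, start)
      ends <- c(ends, i)
    }
  }
  if (open) {
    starts <- c(starts, start)
    ends <- c(ends, n + 1L)
  }
  tibble::tibble(start = starts, end = ends)
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Preprocess one heel-strike window
#'
#' Four-stage chain applied to the raw vertical-acceleration segment, in
#' order: (1) mean removal, (2) zero-padding of the tail to the next power
#' of two (so the FFT length is 2^n), (3) multiplication by a Hamming
#' window of the padded length, (4) Savitzky-Golay polynomial smoothing.
#' Mean removal precedes padding so the zero tail does not create a step
#' edge whose spectrum would swamp the soil response.
#'
#' @param signal Numeric vector, one raw strike segment (m/s^2).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window length: odd, greater than
#'   `sg_order`, at most the padded length.
#' @return Numeric vector of length `2^n >= length(signal)` with
#'   attributes `padded_length`, `raw_length` and `filter_params`.
#' @export
#' @examples
#' out <- preprocess_strike(sin(seq(0, 20, length.out = 100)))
#' length(out)  # 128
preprocess_strike <- function(signal, sg_order = 3, sg_window = 11) {
  if (length(signal) == 0) {
    stop_solegait("strike window is empty", "parameter")
  }
  sg_order <- as.integer(sg_order)
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2 == 0 || sg_window <= sg_order) {
    stop_solegait("sg_window must be odd and greater than sg_order", "parameter")
  }
  padded <- next_pow2(length(signal))
  if (sg_window > padded) {
    stop_solegait("sg_window exceeds the padded window length", "parameter")
  }
  x <- signal - mean(signal)
  x <- c(x, numeric(padded - length(x)))
  x <- x * signal::hamming(padded)
  x <- signal::sgolayfilt(x, p = sg_order, n = sg_window)
  structure(
    as.numeric(x),
    padded_length = padded,
    raw_length = length(signal),
    filter_params = c(order = sg_order, window = sg_window)
  )
}

#' Preprocess every strike in a strike table
#'
#' Applies [preprocess_strike()] to each `signal`, adding `processed`
#' (list column) and `padded_length` columns.
#'
#' @param strikes Tibble from [detect_strikes()] (or the simulators).
#' @inheritParams preprocess_strike
#' @return `strikes` with `processed` and `padded_length` columns.
#' @export
preprocess_strikes <- function(strikes, sg_order = 3, sg_window = 11) {
  strikes |>
    dplyr::mutate(
      processed = purrr::map(.data$signal, preprocess_strike,
        sg_order = sg_order, sg_window = sg_window
      ),
      padded_length = purrr::map_dbl(.data$processed, length)
    )
}
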