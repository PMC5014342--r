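#' Default synthetic soil profiles
#'
#' Six soil classes modelled as damped-resonance mixtures, emulating the
#' qualitative physics of heel-strike vibration: a hard slab (concrete)
#' rings at a single high frequency with little damping and almost no
#' grain noise, while granular soils respond lower, broader and noisier
#' because the grains shear against each other under the impact.  Two of
#' the granular classes (sand and stone dust) are given neighbouring
#' resonances with very different damping, so their spectral centroids
#' crowd each other while their time-domain texture (decay speed, hence
#' kurtosis) stays distinct -- the regime in which the centroid alone
#' under-performs the full weighted-feature level.
#'
#' @param path Optional YAML profile library to read instead of the
#'   built-in set (same shape as `inst/extdata/soil_profiles.yaml`).
#' @return Tibble: `soil`, `resonance_freqs` (Hz, list), `damping_ratios`
#'   (list, in (0, 1)), `grain_noise` (relative amplitude),
#'   `impact_amp` (m/s^2), `duration_ms`.
#' @export
default_soil_profiles <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    return(dplyr::bind_rows(lapply(raw, function(p) {
      tibble::tibble(
        soil = p$soil,
        resonance_freqs = list(as.numeric(unlist(p$resonance_freqs))),
        damping_ratios = list(as.numeric(unlist(p$damping_ratios))),
        grain_noise = p$grain_noise,
        impact_amp = p$impact_amp,
        duration_ms = p$duration_ms
      )
    })))
  }
  tibble::tibble(
    soil = c("concrete", "parquet", "broken_stone", "stone_dust", "sand", "snow"),
    resonance_freqs = list(420, 320, c(90, 230), 150, 150, 60),
    damping_ratios = list(0.010, 0.030, c(0.050, 0.060), 0.060, 0.035, 0.100),
    grain_noise = c(0.005, 0.008, 0.02, 0.01, 0.01, 0.02),
    impact_amp = c(28, 20, 15, 4, 8, 5),
    duration_ms = c(60, 80, 120, 90, 150, 180)
  )
}

#' Simulate one heel-strike vibration window
#'
#' A sum of exponentially damped sinusoids at the profile's resonances
#' plus white grain noise, gated by a half-sine impact envelope.  Pure
#' function of (profile, rate, seed).
#'
#' @param profile One-row tibble (or list) with the fields of
#'   [default_soil_profiles()].
#' @param rate Sampling rate in Hz (default 1000, the strike-acquisition
#'   regime).
#' @param seed Integer seed.
#' @return One-row strike tibble (`strike`, `start`, `end`, `soil`,
#'   `signal`), compatible with [strike_features()].
#' @export
simulate_strike <- function(profile, rate = 1000, seed = 1L) {
  freqs <- unlist(profile$resonance_freqs)
  zetas <- unlist(profile$damping_ratios)
  if (any(freqs >= rate / 2)) {
    stop_solegait("resonance frequency at or above Nyquist", "parameter")
  }
  if (any(zetas <= 0 | zetas >= 1)) {
    stop_solegait("damping ratios must lie in (0, 1)", "parameter")
  }
  n <- max(4L, as.integer(round(profile$duration_ms / 1000 * rate)))
  tt <- (seq_len(n) - 1) / rate
  osc <- rowSums(vapply(
    seq_along(freqs),
    function(k) sin(2 * pi * freqs[k] * tt) * exp(-2 * pi * freqs[k] * zetas[k] * tt),
    numeric(n)
  )) / length(freqs)
  set.seed(seed)
  noise <- profile$grain_noise * rnorm(n)
  env <- sin(pi * (seq_len(n) - 1) / (n - 1))
  tibble::tibble(
    strike = 1L,
    start = 1L,
    end = n + 1L,
    soil = as.character(profile$soil),
    signal = list(profile$impact_amp * (osc + noise) * env)
  )
}

#' Simulate a labelled multi-soil strike dataset
#'
#' One recording per soil class: `n_per_class` strikes embedded in a
#' continuous trace with matching FSR bursts (half-sine contact force
#' under each strike), so the dataset exercises the full detection
#' pipeline.  Ground-truth strike boundaries travel in each recording's
#' metadata (`strike_start`, `strike_end`).
#'
#' @param profiles Profile tibble, see [default_soil_profiles()];
#'   duplicate soil names are an error.
#' @param n_per_class Strikes per soil (default 13, one walking pass per
#'   surface); 0 returns an empty dataset.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; each strike derives its own sub-seed so the
#'   dataset is reproducible strike-for-strike.
#' @return Tibble with one row per soil: `soil`, `recording` (list of
#'   [recording()] objects).
#' @export
simulate_soil_dataset <- function(profiles = default_soil_profiles(),
                                  n_per_class = 13, rate = 1000, seed = 42L) {
  if (anyDuplicated(profiles$soil)) {
    stop_solegait("duplicate soil names in profile set", "parameter")
  }
  if (n_per_class == 0) {
    return(tibble::tibble(soil = character(), recording = list()))
  }
  gap_n <- as.integer(round(0.30 * rate))
  lead_n <- as.integer(round(0.20 * rate))
  rows <- purrr::imap(seq_len(nrow(profiles)), function(i, ...) {
    profile <- profiles[i, ]
    strikes <- purrr::map(seq_len(n_per_class), function(j) {
      simulate_strike(profile, rate = rate, seed = seed + 1000L * i + j)
    })
    lens <- purrr::map_int(strikes, function(s) length(s$signal[[1]]))
    total <- lead_n + sum(lens + gap_n)
    accel_z <- numeric(total)
    fsr <- numeric(total)
    starts <- integer(n_per_class)
    pos <- lead_n + 1L
    for (j in seq_len(n_per_class)) {
      idx <- pos:(pos + lens[j] - 1L)
      accel_z[idx] <- strikes[[j]]$signal[[1]]
      fsr[idx] <- 100 * sin(pi * (seq_len(lens[j]) - 1) / (lens[j] - 1))
      starts[j] <- pos
      pos <- pos + lens[j] + gap_n
    }
    rec <- recording(
      tibble::tibble(
        accel_x = numeric(total), accel_y = numeric(total),
        accel_z = accel_z, fsr_heel = fsr
      ),
      sample_rate = rate,
      meta = list(
        soil = profile$soil,
        strike_start = starts,
        strike_end = starts + lens
      )
    )
    tibble::tibble(soil = profile$soil, recording = list(rec))
  })
  dplyr::bind_rows(rows)
}

#' Extract labelled strikes from a simulated soil dataset
#'
#' Runs [detect_strikes()] over every recording and stacks the windows
#' with their soil labels -- the input expected by [strike_features()].
#'
#' @param dataset Tibble from [simulate_soil_dataset()] (or any tibble
#'   with `soil` and `recording` columns).
#' @inheritParams detect_strikes
#' @return A strike tibble with a `soil` column.
#' @export
dataset_strikes <- function(dataset, onset_frac = 0.3, release_frac = 0.1,
                            max_window_ms = 250) {
  dplyr::bind_rows(purrr::map(dataset$recording, detect_strikes,
    onset_frac = onset_frac, release_frac = release_frac,
    max_window_ms = max_window_ms
  ))
}

#' Gait profile for the TUG simulator
#'
#' Parameterizes the statistical structure the variability analysis
#' assumes: how many strides, at what cadence and stride length, with how
#' much injected variability, and how long the postural phases last.  The
#' default is a healthy-adult profile that completes the TUG in under
#' 10 s: 6 strides (3 m out and back at about 1 m strides), 120 steps/min
#' and 2% variability.
#'
#' @param n_strides Total measured strides (even, at least 2).
#' @param cadence_mean Nominal cadence in steps/min.
#' @param cadence_cv Nominal step-interval coefficient of variation, %.
#' @param stride_len_mean Nominal stride length in metres.
#' @param stride_cv Nominal stride-length coefficient of variation, %.
#' @param sit_to_stand,turn,stand_to_sit Phase durations in seconds.  The
#'   turn is realized as 3 slowed step intervals of `turn/3` each, floored
#'   at 1.5 step intervals so the slow-down is always detectable.
#' @param seed Default seed for [simulate_tug()].
#' @return A `gait_profile` list.
#' @export
gait_profile <- function(n_strides = 6, cadence_mean = 120, cadence_cv = 2,
                         stride_len_mean = 1.0, stride_cv = 2,
                         sit_to_stand = 0.8, turn = 2.25, stand_to_sit = 0.8,
                         seed = 1L) {
  if (n_strides < 2 || n_strides %% 2 != 0) {
    stop_solegait("n_strides must be an even number >= 2", "parameter")
  }
  if (cadence_mean <= 0 || stride_len_mean <= 0 || cadence_cv < 0 || stride_cv < 0) {
    stop_solegait("gait profile values must be positive (CVs non-negative)", "parameter")
  }
  structure(
    list(
      n_strides = as.integer(n_strides),
      cadence_mean = cadence_mean,
      cadence_cv = cadence_cv,
      stride_len_mean = stride_len_mean,
      stride_cv = stride_cv,
      sit_to_stand = sit_to_stand,
      turn = turn,
      stand_to_sit = stand_to_sit,
      seed = as.integer(seed)
    ),
    class = "gait_profile"
  )
}

#' Simulate a full TUG trial with ground truth
#'
#' Builds a 100 Hz insole recording of one Timed Up and Go trial:
#' sit-to-stand load ramp, out walk, slowed turn intervals, return walk
#' and stand-to-sit unload ramp.  Step events appear as half-sine bumps in
#' the vertical acceleration with matching FSR contact bursts.  Step
#' intervals are drawn with the profile's nominal cadence CV (each
#' interval rounded to the sample grid so a zero-CV profile measures as
#' zero), and per-stride bump amplitudes are solved numerically so that
#' the stride-length estimator applied to the generated samples recovers
#' the drawn stride lengths exactly at zero noise.
#'
#' @param profile A [gait_profile()].
#' @param rate Sampling rate in Hz (default 100, the TUG regime).
#' @param seed Integer seed (defaults to the profile's).
#' @param accel_noise_sd,fsr_noise_sd Optional additive white noise
#'   (m/s^2 / force units); defaults are noise-free.
#' @return List with `recording` (a [recording()]) and `truth` (list:
#'   `phases` tibble of the true boundary times, `step_times`,
#'   `stride_lengths`, the nominal cadence and CVs).
#' @export
simulate_tug <- function(profile = gait_profile(), rate = 100,
                         seed = profile$seed, accel_noise_sd = 0,
                         fsr_noise_sd = 0) {
  set.seed(seed)
  h <- 1 / rate
  grid <- function(x) round(x / h) * h
  T0 <- 60 / profile$cadence_mean
  S <- profile$n_strides / 2 # strides per leg
  m_leg <- profile$n_strides + 1 # steps per leg (2S + 1)

  draw_intervals <- function(k) {
    iv <- rnorm(k, T0, profile$cadence_cv / 100 * T0)
    iv <- pmax(iv, 2 * h)
    grid(iv)
  }
  iv_out <- draw_intervals(m_leg - 1)
  iv_back <- draw_intervals(m_leg - 1)
  turn_iv <- grid(rep(max(profile$turn / 3, 1.5 * T0), 3))

  sit_pre <- 1.0
  t_start <- grid(sit_pre)
  first_step <- grid(t_start + profile$sit_to_stand)
  step_times <- first_step + c(0, cumsum(c(iv_out, turn_iv, iv_back)))
  last_step <- step_times[length(step_times)]
  t_end <- grid(last_step + profile$stand_to_sit)
  total_t <- t_end + 1.0
  n <- as.integer(round(total_t / h)) + 1L
  tvec <- (seq_len(n) - 1) * h
  idx_of <- function(tm) as.integer(round(tm / h)) + 1L

  # ---- FSR channel: baseline load, ramps, standing plateaus, bursts ----
  fsr <- rep(2, n)
  ramp_n <- as.integer(round(0.4 * rate))
  i0 <- idx_of(t_start)
  fsr[i0:(i0 + ramp_n)] <- 2 + (100 - 2) * (0:ramp_n) / ramp_n
  plateau_hw <- as.integer(round(0.15 * rate))
  fsr[(i0 + ramp_n):idx_of(step_times[1])] <- 100
  for (tm in step_times) {
    ic <- idx_of(tm)
    span <- max(1L, ic - plateau_hw):min(n, ic + plateau_hw)
    fsr[span] <- pmax(fsr[span], 100 * sin(pi * (seq_along(span) - 1) / (length(span) - 1)))
  }
  i1 <- idx_of(last_step)
  i2 <- idx_of(t_end)
  fsr[i1:(i2 - ramp_n)] <- 100
  fsr[(i2 - ramp_n):i2] <- 100 - (100 - 2) * (0:ramp_n) / ramp_n
  if (fsr_noise_sd > 0) fsr <- pmax(0, fsr + rnorm(n, 0, fsr_noise_sd))

  # ---- acceleration channel: one half-sine bump per step --------------
  # Two bump shapes: wide bumps on the stride-interior (even) steps carry
  # the solved stride mass; narrow-but-tall bumps on the stride-bounding
  # (odd) and turn steps keep their mass contribution small (so the
  # per-stride amplitude solve always has a positive root) while staying
  # prominent enough for peak detection.
  mk_bump <- function(hw) sin(pi * (0:(2 * hw)) / (2 * hw))
  bump_hw <- as.integer(round(0.12 * rate))
  bump <- mk_bump(bump_hw)
  narrow_hw <- max(2L, as.integer(round(0.04 * rate)))
  narrow <- mk_bump(narrow_hw)
  bump_at <- function(acc, ic, amp, shape = bump, hw = bump_hw) {
    span <- (ic - hw):(ic + hw)
    keep <- span >= 1 & span <= n
    acc[span[keep]] <- acc[span[keep]] + amp * shape[keep]
    acc
  }

  # Target stride lengths and the per-step amplitudes that encode them.
  sl_target <- pmax(rnorm(profile$n_strides,
    profile$stride_len_mean,
    profile$stride_cv / 100 * profile$stride_len_mean
  ), 0.2)
  m_target <- (sl_target / 0.98)^3

  # Steps are indexed globally; odd steps within a leg bound the strides
  # and carry a fixed reference amplitude, even steps are solved per
  # stride so the stride-length estimator recovers sl_target exactly.
  step_leg <- c(rep(1L, m_leg), rep(0L, 3 - 1), rep(2L, m_leg))
  stopifnot(length(step_leg) == length(step_times))
  # Reference amplitude for the stride-bounding (odd) and turn steps: mass
  # capped at a quarter of the smallest stride target so the solved
  # mid-step bump always has a positive root.
  N_stride <- as.integer(round(2 * T0 * rate))
  A0 <- 0.25 * min(m_target) * N_stride / sum(narrow)

  amps <- rep(A0, length(step_times))
  wide <- rep(FALSE, length(step_times))
  stride_no <- 0L
  for (leg in 1:2) {
    leg_steps <- which(step_leg == leg)
    for (j in seq_len(S)) {
      stride_no <- stride_no + 1L
      a <- leg_steps[2 * j - 1]
      b <- leg_steps[2 * j + 1]
      ia <- idx_of(step_times[a])
      ib <- idx_of(step_times[b])
      seg_idx <- ia:(ib - 1L)
      base <- numeric(n)
      base <- bump_at(base, ia, A0, narrow, narrow_hw)
      base <- bump_at(base, ib, A0, narrow, narrow_hw)
      base_seg <- base[seg_idx]
      mid <- leg_steps[2 * j]
      wide[mid] <- TRUE
      unit <- numeric(n)
      unit <- bump_at(unit, idx_of(step_times[mid]), 1)
      unit_seg <- unit[seg_idx]
      g <- function(e) {
        v <- base_seg + e * unit_seg
        mean(abs(v - mean(v))) - m_target[stride_no]
      }
      amps[mid] <- uniroot(g, c(0, 1e4 * A0), extendInt = "upX", tol = 1e-12)$root
    }
  }

  accel_z <- numeric(n)
  for (k in seq_along(step_times)) {
    accel_z <- if (wide[k]) {
      bump_at(accel_z, idx_of(step_times[k]), amps[k])
    } else {
      bump_at(accel_z, idx_of(step_times[k]), amps[k], narrow, narrow_hw)
    }
  }
  if (accel_noise_sd > 0) accel_z <- accel_z + rnorm(n, 0, accel_noise_sd)

  rec <- recording(
    tibble::tibble(
      t = tvec,
      accel_x = numeric(n), accel_y = numeric(n), accel_z = accel_z,
      fsr_heel = fsr
    ),
    sample_rate = rate,
    meta = list(trial = "synthetic_tug", seed = seed)
  )

  truth <- list(
    phases = tibble::tibble(
      t_start = t_start,
      t_stand_end = step_times[1],
      t_turn_start = step_times[m_leg],
      t_turn_end = step_times[m_leg + 3],
      t_walkback_end = last_step,
      t_end = t_end,
      tug_time = t_end - t_start
    ),
    step_times = step_times,
    stride_lengths = sl_target,
    cadence_mean = profile$cadence_mean,
    cadence_cv = profile$cadence_cv,
    stride_cv = profile$stride_cv
  )
  list(recording = rec, truth = truth)
}
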