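# Shared fixtures: tiny recordings and independent brute-force oracles.

# Minimal valid recording from channel vectors.
make_recording <- function(accel_z, fsr, rate = 100, meta = list()) {
  recording(
    tibble::tibble(accel_z = accel_z, fsr_heel = fsr),
    sample_rate = rate, meta = meta
  )
}

# Rectangular FSR burst train: n_bursts bursts of burst_n samples separated
# by gap_n zeros.
burst_train <- function(n_bursts, burst_n = 50, gap_n = 100, height = 10) {
  x <- numeric(gap_n)
  for (i in seq_len(n_bursts)) {
    x <- c(x, rep(height, burst_n), numeric(gap_n))
  }
  x
}

# Brute-force threshold-crossing window count (independent of the package's
# hysteresis scanner): state machine written the obvious way.
oracle_window_count <- function(x, on, off) {
  open <- FALSE
  count <- 0L
  for (v in x) {
    if (!open && v >= on) {
      open <- TRUE
      count <- count + 1L
    } else if (open && v < off) {
      open <- FALSE
    }
  }
  count
}

# Brute-force lamina centroid over spectrum bins by direct double summation.
oracle_lamina_centroid <- function(freq, mag) {
  num_x <- 0
  num_y <- 0
  den <- 0
  for (i in seq_along(freq)) {
    num_x <- num_x + freq[i] * mag[i]
    num_y <- num_y + mag[i] * mag[i] / 2
    den <- den + mag[i]
  }
  c(sx = num_x / den, sy = num_y / den)
}

# Two-pass moment computation of the coefficient of variation.
oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  100 * sqrt(ss / (n - 1)) / m
}

# Spectral flatness (geometric / arithmetic mean of magnitudes).
spectral_flatness <- function(mag) {
  mag <- mag[mag > 0]
  exp(mean(log(mag))) / mean(mag)
}
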