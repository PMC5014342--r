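#' One-sided magnitude spectrum of a processed strike
#'
#' FFT of the preprocessed window with "mean absolute value" scaling:
#' magnitudes are divided by the padded length, so a unit impulse gives a
#' flat spectrum at 1/N.  Bins run from 0 Hz to Nyquist.
#'
#' @param processed Numeric vector from [preprocess_strike()] (length 2^n).
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with `freq` (Hz) and `mag` (non-negative) columns,
#'   `N/2 + 1` rows.
#' @export
#' @examples
#' sp <- compute_spectrum(preprocess_strike(rnorm(100)), 1000)
#' nrow(sp)  # 65
compute_spectrum <- function(processed, sample_rate) {
  n <- length(processed)
  if (n < 2 || bitwAnd(n, n - 1L) != 0) {
    stop_solegait("processed window length must be a power of two", "parameter")
  }
  mags <- Mod(stats::fft(processed))[seq_len(n / 2 + 1)] / n
  tibble::tibble(
    freq = seq(0, sample_rate / 2, length.out = n / 2 + 1),
    mag = mags
  )
}

#' Spectral centroid of a magnitude spectrum
#'
#' Two conventions for the centroid coordinate (Sx, Sy) used as a soil
#' signature:
#' \describe{
#'   \item{`area` (default)}{the region under the magnitude curve is a
#'     lamina of uniform density: `Sx = sum(f * m) / sum(m)` and
#'     `Sy = sum(m^2 / 2) / sum(m)`.  Varies with spectral shape.}
#'   \item{`point`}{each occupied bin is a unit point mass: `Sx` and `Sy`
#'     are plain means of the bin frequencies and magnitudes over bins
#'     whose magnitude exceeds `1e-12 * max(mag)`.}
#' }
#'
#' @param spectrum Tibble from [compute_spectrum()].
#' @param method `"area"` or `"point"`.
#' @return One-row tibble with `sx` (Hz) and `sy` (magnitude units).
#' @export
#' @examples
#' sp <- tibble::tibble(freq = c(0, 50, 100), mag = c(0, 2, 0))
#' spectral_centroid(sp)  # sx = 50, sy = 1
spectral_centroid <- function(spectrum, method = c("area", "point")) {
  method <- match.arg(method)
  m <- spectrum$mag
  f <- spectrum$freq
  if (all(m <= 0)) {
    stop_solegait("centroid undefined for an all-zero spectrum", "degenerate")
  }
  if (method == "area") {
    total <- sum(m)
    tibble::tibble(sx = sum(f * m) / total, sy = sum(m^2 / 2) / total)
  } else {
    keep <- m > 1e-12 * max(m)
    tibble::tibble(sx = mean(f[keep]), sy = mean(m[keep]))
  }
}

#' Per-strike feature vector
#'
#' The features entering the weighted differentiation level: the spectral
#' centroid coordinates plus time-domain statistics of the preprocessed
#' window.  Moments use population (1/n) denominators; kurtosis is the
#' standardized fourth central moment (Gaussian -> 3).  A zero-variance
#' window gets kurtosis 0 with `zero_variance = TRUE`.
#'
#' @param processed Numeric vector from [preprocess_strike()].
#' @param spectrum Tibble from [compute_spectrum()]; computed from
#'   `processed` when omitted (needs `sample_rate`).
#' @param sample_rate Sampling rate in Hz (only used when `spectrum` is
#'   omitted).
#' @param centroid_method Passed to [spectral_centroid()].
#' @return One-row tibble: `sx`, `sy`, `mean`, `std`, `variance`,
#'   `kurtosis`, `zero_variance`.
#' @export
extract_features <- function(processed, spectrum = NULL, sample_rate = NULL,
                             centroid_method = c("area", "point")) {
  centroid_method <- match.arg(centroid_method)
  if (is.null(spectrum)) {
    if (is.null(sample_rate)) {
      stop_solegait("supply either a spectrum or a sample_rate", "parameter")
    }
    spectrum <- compute_spectrum(processed, sample_rate)
  }
  x <- as.numeric(processed)
  n <- length(x)
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  zero_var <- m2 < 1e-24
  kurt <- if (zero_var) 0 else (sum((x - mu)^4) / n) / m2^2
  cent <- if (all(spectrum$mag <= 0)) {
    tibble::tibble(sx = 0, sy = 0)
  } else {
    spectral_centroid(spectrum, method = centroid_method)
  }
  tibble::tibble(
    sx = cent$sx,
    sy = cent$sy,
    mean = mu,
    std = sqrt(m2),
    variance = m2,
    kurtosis = kurt,
    zero_variance = zero_var
  )
}

SOIL_FEATURES <- c("sx", "sy", "mean", "std", "variance", "kurtosis")

#' Full strike-to-feature pipeline for a strike table
#'
#' Runs preprocessing, spectrum and feature extraction for every strike,
#' returning one feature row per strike with its `soil` label carried
#' along.
#'
#' @param strikes Tibble from [detect_strikes()] or [simulate_strike()].
#' @param sample_rate Sampling rate of the strike signals in Hz.
#' @param sg_order,sg_window Savitzky-Golay parameters, see
#'   [preprocess_strike()].
#' @param centroid_method Passed to [spectral_centroid()].
#' @return Tibble: `soil`, `strike`, and the columns of
#'   [extract_features()].
#' @export
strike_features <- function(strikes, sample_rate, sg_order = 3, sg_window = 11,
                            centroid_method = c("area", "point")) {
  centroid_method <- match.arg(centroid_method)
  if (nrow(strikes) == 0) {
    stop_solegait("no strikes to featurize", "parameter")
  }
  feats <- purrr::map(strikes$signal, function(sig) {
    proc <- preprocess_strike(sig, sg_order = sg_order, sg_window = sg_window)
    extract_features(proc,
      sample_rate = sample_rate,
      centroid_method = centroid_method
    )
  })
  dplyr::bind_cols(
    tibble::tibble(
      soil = strikes$soil %||% NA_character_,
      strike = strikes$strike
    ),
    dplyr::bind_rows(feats)
  )
}
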