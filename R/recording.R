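#' Construct an insole recording
#'
#' A recording is a tibble with one row per sample: a time column `t`
#' (seconds, uniform grid), acceleration channels `accel_x`/`accel_y`/
#' `accel_z` (m/s^2), one or more non-negative force channels named
#' `fsr_*` (arbitrary sensor units) and an optional dimensionless `bend`
#' column.  The sampling rate and free-form metadata (subject id, soil
#' label, trial id, ...) travel as attributes so the object stays a plain
#' tibble for dplyr/ggplot2 work.
#'
#' @param data Data frame of channel columns.  `t` is regenerated from
#'   `sample_rate` when absent.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param meta Named list of metadata.
#' @param validate Check invariants (uniform grid, non-negative FSR,
#'   mandatory `accel_z` and at least one `fsr_*` channel).
#' @return A `recording` tibble.
#' @export
#' @examples
#' rec <- recording(
#'   data.frame(accel_z = c(0, 1, 0), fsr_heel = c(0, 5, 0)),
#'   sample_rate = 100
#' )
#' sample_rate(rec)
recording <- function(data, sample_rate, meta = list(), validate = TRUE) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || !is.finite(sample_rate) ||
      sample_rate <= 0) {
    stop_solegait("sample_rate must be a positive number", "format")
  }
  data <- tibble::as_tibble(data)
  if (!"t" %in% names(data)) {
    data <- dplyr::mutate(data, t = (dplyr::row_number() - 1) / sample_rate)
  }
  data <- dplyr::select(data, "t", dplyr::everything())
  out <- structure(
    data,
    sample_rate = as.numeric(sample_rate),
    meta = meta,
    class = c("recording", class(data))
  )
  if (validate) validate_recording(out)
  out
}

#' @rdname recording
#' @param rec A `recording`.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate")

#' @rdname recording
#' @export
recording_meta <- function(rec) attr(rec, "meta") %||% list()

fsr_channels <- function(rec) grep("^fsr", names(rec), value = TRUE)

accel_channels <- function(rec) {
  intersect(c("accel_x", "accel_y", "accel_z"), names(rec))
}

#' Validate a recording's invariants
#'
#' Checks that all channels share a length of at least 2, that `t` is a
#' strictly increasing uniform grid at `1/sample_rate` spacing (1e-6
#' relative tolerance), that FSR values are non-negative, and that the
#' mandatory channels (`accel_z`, at least one `fsr_*`) are present.
#'
#' @param rec A `recording`.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  if (nrow(rec) < 2) {
    stop_solegait("recording must contain at least 2 samples", "format")
  }
  if (!"accel_z" %in% names(rec)) {
    stop_solegait("mandatory channel accel_z is missing", "format")
  }
  fsr <- fsr_channels(rec)
  if (length(fsr) == 0) {
    stop_solegait("at least one fsr_* channel is required", "format")
  }
  for (ch in fsr) {
    if (any(rec[[ch]] < 0, na.rm = TRUE)) {
      stop_solegait(paste0("FSR channel ", ch, " has negative values"), "format")
    }
  }
  rate <- sample_rate(rec)
  dt <- diff(rec$t)
  if (any(dt <= 0)) {
    stop_solegait("timestamps must be strictly increasing", "timing")
  }
  expected <- 1 / rate
  if (any(abs(dt - expected) > 1e-6 * expected)) {
    stop_solegait(
      "timestamps are not uniform at 1/sample_rate spacing (1e-6 relative tolerance)",
      "timing"
    )
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  rate <- sample_rate(x)
  meta <- recording_meta(x)
  cat(sprintf(
    "<recording> %d samples @ %g Hz (%.3f s), channels: %s\n",
    nrow(x), rate, (nrow(x) - 1) / rate,
    paste(setdiff(names(x), "t"), collapse = ", ")
  ))
  scalars <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  if (length(scalars) > 0) {
    cat("  meta:", paste(names(scalars), unlist(scalars), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

STANDARD_CHANNELS <- c("t", "accel_x", "accel_y", "accel_z", "bend")

G_TO_MS2 <- 9.80665

#' Read an insole recording
#'
#' CSV files carry `# key=value` comment-header lines (`sample_rate` plus
#' metadata); JSON-Lines files start with a header object followed by one
#' sample object per line.  Unknown columns are preserved into the
#' recording metadata (`extra_channels`).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @param rate Override the declared sampling rate (Hz); timestamps are
#'   regenerated when the file declares none.
#' @param accel_in_g If `TRUE`, stored acceleration is in g and converted
#'   to m/s^2 on read.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "jsonl"), rate = NULL,
                           accel_in_g = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_solegait(paste0("file not found: ", path), "io")
  }
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    header <- parse_comment_header(path)
    data <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
    meta <- header$meta
    declared_rate <- header$sample_rate
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 2) {
      stop_solegait("jsonl recording needs a header line plus samples", "format")
    }
    header <- jsonlite::fromJSON(lines[1])
    data <- tibble::as_tibble(jsonlite::stream_in(
      textConnection(lines[-1]),
      verbose = FALSE
    ))
    meta <- as.list(header$meta %||% list())
    declared_rate <- header$sample_rate
  }
  rate <- rate %||% declared_rate
  if (is.null(rate)) {
    stop_solegait("no sample_rate declared in file and none supplied", "format")
  }
  if (!"accel_z" %in% names(data)) {
    stop_solegait("mandatory channel accel_z is missing", "format")
  }
  if (!any(grepl("^fsr", names(data)))) {
    stop_solegait("at least one fsr_* channel is required", "format")
  }
  known <- names(data) %in% STANDARD_CHANNELS | grepl("^fsr", names(data))
  if (any(!known)) {
    meta$extra_channels <- data[!known]
    data <- data[known]
  }
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.double))
  if (isTRUE(accel_in_g)) {
    for (ch in intersect(c("accel_x", "accel_y", "accel_z"), names(data))) {
      data[[ch]] <- data[[ch]] * G_TO_MS2
    }
  }
  if (!"t" %in% names(data)) {
    data$t <- (seq_len(nrow(data)) - 1) / rate
  }
  recording(data, sample_rate = rate, meta = meta)
}

parse_comment_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  meta <- list()
  sample_rate <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    body <- sub("^#\\s*", "", line)
    if (!grepl("=", body, fixed = TRUE)) next
    key <- sub("=.*$", "", body)
    value <- sub("^[^=]*=", "", body)
    if (key == "sample_rate") {
      sample_rate <- as.numeric(value)
    } else {
      num <- suppressWarnings(as.numeric(value))
      meta[[key]] <- if (!is.na(num)) num else value
    }
  }
  list(sample_rate = sample_rate, meta = meta)
}

#' Write an insole recording
#'
#' Inverse of [read_recording()]: the written file re-reads to an equal
#' recording (channels bit-for-bit, scalar metadata preserved).
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  meta <- recording_meta(rec)
  scalars <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  data <- tibble::as_tibble(unclass(rec))
  if (format == "csv") {
    # Doubles are written with 17 significant digits so the file re-reads
    # to bit-identical channel values.
    fmt_col <- function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    }
    body <- do.call(paste, c(lapply(data, fmt_col), list(sep = ",")))
    lines <- c(
      sprintf("# sample_rate=%.17g", sample_rate(rec)),
      sprintf("# %s=%s", names(scalars), vapply(scalars, as.character, character(1))),
      paste(names(data), collapse = ","),
      body
    )
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(
      jsonlite::toJSON(
        list(sample_rate = sample_rate(rec), meta = scalars),
        auto_unbox = TRUE, digits = NA
      ),
      con
    )
    jsonlite::stream_out(as.data.frame(data), con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Linear interpolation onto a uniform grid at `target_rate`, preserving
#' the duration to within one sample period.  Bridges the two acquisition
#' regimes (about 1 kHz for soil strikes, 100 Hz for TUG trials).
#'
#' @param rec A [recording()].
#' @param target_rate New sampling rate in Hz (positive).
#' @return A [recording()] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1 || !is.finite(target_rate) ||
      target_rate <= 0) {
    stop_solegait("target_rate must be a positive number", "parameter")
  }
  rate <- sample_rate(rec)
  if (isTRUE(all.equal(rate, target_rate))) {
    return(rec)
  }
  duration <- (nrow(rec) - 1) / rate
  n_new <- floor(duration * target_rate + 1e-9) + 1
  t_new <- rec$t[1] + (seq_len(n_new) - 1) / target_rate
  channels <- setdiff(names(rec), "t")
  out <- tibble::as_tibble(c(
    list(t = t_new),
    lapply(rec[channels], function(y) approx(rec$t, y, xout = t_new, rule = 2)$y)
  ))
  recording(out, sample_rate = target_rate, meta = recording_meta(rec))
}

#' Plot a recording's channels
#'
#' Faceted time-series view of every channel (acceleration, FSR, bend).
#'
#' @param object A [recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recording <- function(object, ...) {
  long <- tidyr_pivot_channels(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL)
}

# Minimal long-format pivot (avoids a tidyr dependency for one reshape).
tidyr_pivot_channels <- function(rec) {
  channels <- setdiff(names(rec), "t")
  dplyr::bind_rows(lapply(channels, function(ch) {
    tibble::tibble(t = rec$t, channel = ch, value = rec[[ch]])
  })) |>
    dplyr::mutate(channel = factor(.data$channel, levels = channels))
}

#' @importFrom rlang .data
NULL
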