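test_that("recording construction validates invariants", {
  rec <- make_recording(c(0, 1, 0), c(0, 5, 0))
  expect_s3_class(rec, "recording")
  expect_equal(nrow(rec), 3)
  expect_equal(sample_rate(rec), 100)
  expect_equal(rec$t, c(0, 0.01, 0.02))

  expect_error(
    recording(tibble::tibble(accel_z = 1:3), sample_rate = 100),
    class = "solegait_error_format"
  )
  expect_error(
    recording(tibble::tibble(fsr_heel = c(1, 2, 3)), sample_rate = 100),
    class = "solegait_error_format"
  )
  expect_error(
    make_recording(c(0, 1, 0), c(0, -5, 0)),
    class = "solegait_error_format"
  )
  expect_error(
    recording(
      tibble::tibble(t = c(0, 0.01, 0.5), accel_z = 1:3, fsr_heel = 0:2),
      sample_rate = 100
    ),
    class = "solegait_error_timing"
  )
  expect_error(make_recording(1, 1), class = "solegait_error_format")
})

test_that("csv files round-trip bit-for-bit with header metadata", {
  rec <- make_recording(rnorm(25), abs(rnorm(25)),
    rate = 250,
    meta = list(soil = "sand", subject = "s01")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(as.data.frame(rec), as.data.frame(back))
  expect_equal(sample_rate(back), 250)
  expect_equal(recording_meta(back)$soil, "sand")
  expect_equal(recording_meta(back)$subject, "s01")
})

test_that("jsonl files carry a header object then one sample per line", {
  rec <- make_recording(c(0, 1, 0), c(0, 5, 0), meta = list(trial = "t1"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_recording(rec, path)
  lines <- readLines(path)
  expect_length(lines, 1 + nrow(rec))
  hdr <- jsonlite::fromJSON(lines[1])
  expect_equal(hdr$sample_rate, 100)
  expect_equal(hdr$meta$trial, "t1")
  first <- jsonlite::fromJSON(lines[2])
  expect_named(first, c("t", "accel_z", "fsr_heel"))
  back <- read_recording(path)
  expect_equal(back$accel_z, rec$accel_z)
  expect_equal(back$fsr_heel, rec$fsr_heel)
})

test_that("reading rejects files without mandatory channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_rate=100", "t,accel_z", "0,1", "0.01,2", "0.02,1"), path)
  expect_error(read_recording(path), class = "solegait_error_format")
  writeLines(c("# sample_rate=100", "t,fsr_heel", "0,1", "0.01,2", "0.02,1"), path)
  expect_error(read_recording(path), class = "solegait_error_format")
  expect_error(read_recording("/nonexistent/file.csv"), class = "solegait_error_io")
})

test_that("unknown columns are preserved into metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c(
      "# sample_rate=100", "t,accel_z,fsr_heel,gyro_x",
      "0,1,0,9", "0.01,2,5,8", "0.02,1,0,7"
    ),
    path
  )
  rec <- read_recording(path)
  expect_false("gyro_x" %in% names(rec))
  expect_equal(recording_meta(rec)$extra_channels$gyro_x, c(9, 8, 7))
})

test_that("g-unit conversion applies on read when requested", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c("# sample_rate=100", "t,accel_z,fsr_heel", "0,1,0", "0.01,1,5", "0.02,1,0"),
    path
  )
  rec <- read_recording(path, accel_in_g = TRUE)
  expect_equal(rec$accel_z, rep(9.80665, 3))
})

test_that("resampling preserves identity, constants and duration", {
  rec <- make_recording(rnorm(101), abs(rnorm(101)), rate = 100)
  expect_identical(resample_recording(rec, 100), rec)

  const <- make_recording(rep(3.5, 100), rep(2, 100), rate = 100)
  up <- resample_recording(const, 250)
  expect_equal(sample_rate(up), 250)
  expect_true(all(up$accel_z == 3.5))
  expect_lt(
    abs((nrow(up) - 1) / 250 - (nrow(const) - 1) / 100),
    1 / 100
  )
  expect_error(resample_recording(rec, -5), class = "solegait_error_parameter")
})

test_that("a resampled 5 Hz sine matches the analytic sine within 1% RMS", {
  t1 <- seq(0, 1, by = 1 / 1000)
  rec <- make_recording(sin(2 * pi * 5 * t1), rep(1, length(t1)), rate = 1000)
  down <- resample_recording(rec, 100)
  analytic <- sin(2 * pi * 5 * down$t)
  rms_err <- sqrt(mean((down$accel_z - analytic)^2))
  rms_sig <- sqrt(mean(analytic^2))
  expect_lt(rms_err / rms_sig, 0.01)
})

test_that("down-up resampling is exact for constant and linear channels", {
  n <- 101
  rec <- recording(
    tibble::tibble(
      accel_z = seq(0, 5, length.out = n),
      fsr_heel = rep(2, n)
    ),
    sample_rate = 100
  )
  back <- resample_recording(resample_recording(rec, 50), 100)
  expect_equal(back$accel_z, rec$accel_z, tolerance = 1e-12)
  expect_equal(back$fsr_heel, rec$fsr_heel, tolerance = 1e-12)
})
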