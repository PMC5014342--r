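test_that("TUG phase boundaries land within a quarter second of ground truth", {
  for (s in c(2, 5, 21)) {
    sim <- simulate_tug(gait_profile(), seed = s)
    ph <- segment_tug(sim$recording)
    truth <- sim$truth$phases
    for (b in c(
      "t_start", "t_stand_end", "t_turn_start", "t_turn_end",
      "t_walkback_end", "t_end"
    )) {
      expect_lt(abs(ph[[b]] - truth[[b]]), 0.25)
    }
    expect_true(all(diff(as.numeric(ph[1, 1:6])) > 0))
  }
})

test_that("a healthy synthetic trial completes in under ten seconds", {
  sim <- simulate_tug(gait_profile(), seed = 5)
  ph <- segment_tug(sim$recording)
  expect_lt(ph$tug_time, 10)
  expect_equal(categorize_tug(ph), "normal")
})

test_that("segmentation fails loudly without load or steps", {
  rec <- make_recording(rnorm(500), numeric(500))
  expect_error(segment_tug(rec), class = "solegait_error_segmentation")

  # load plateau but no gait: constant force, flat acceleration
  rec2 <- make_recording(numeric(1000), c(numeric(100), rep(50, 800), numeric(100)))
  expect_error(segment_tug(rec2), class = "solegait_error_segmentation")
})

test_that("step detection recovers the generated step count exactly", {
  for (s in c(3, 8)) {
    sim <- simulate_tug(gait_profile(), seed = s)
    ph <- segment_tug(sim$recording)
    steps <- detect_steps(sim$recording, ph)
    expect_equal(nrow(steps), length(sim$truth$step_times))
    expect_equal(steps$time, sim$truth$step_times, tolerance = 1e-9)
    expect_equal(steps$source[1], "accel")
    expect_true(all(diff(steps$time) > 0))
  }
})

test_that("a corrupted accelerometer falls back to the FSR burst count", {
  sim <- simulate_tug(gait_profile(), seed = 4)
  rec <- sim$recording
  ph <- segment_tug(rec)
  n_true <- length(sim$truth$step_times)
  # halve the step content: erase every other acceleration bump
  drop <- sim$truth$step_times[seq(1, n_true, by = 2)]
  for (tm in drop) {
    i <- which.min(abs(rec$t - tm))
    span <- max(1, i - 20):min(nrow(rec), i + 20)
    rec$accel_z[span] <- 0
  }
  expect_warning(
    steps <- detect_steps(rec, ph),
    class = "solegait_warning_step_source"
  )
  expect_equal(steps$source[1], "fsr")
  expect_gt(nrow(steps), n_true / 2)
})

test_that("a flat trial yields an insufficient-steps error", {
  ph <- tibble::tibble(
    t_start = 0, t_stand_end = 1, t_turn_start = 3, t_turn_end = 4,
    t_walkback_end = 6, t_end = 7, tug_time = 7
  )
  rec <- make_recording(numeric(800), rep(10, 800))
  expect_error(
    suppressWarnings(detect_steps(rec, ph)),
    class = "solegait_error_insufficient_steps"
  )
})

test_that("stride length follows the cube-root acceleration relation", {
  # mean-removed rectified mean of an alternating unit signal is exactly 1
  expect_equal(stride_length(rep(c(1, -1), 50)), 0.98)
  # rectified mean 8 gives twice the unit stride
  expect_equal(stride_length(rep(c(8, -8), 50)), 0.98 * 2)
  expect_equal(stride_length(numeric(30)), 0)
  expect_error(stride_length(numeric(0)), class = "solegait_error_parameter")
})

test_that("gait parameters reduce to closed forms for periodic steps", {
  # 16 steps exactly 0.5 s apart, turn placed outside the step span so all
  # intervals count as walking
  n <- 1200
  accel <- numeric(n)
  fsr <- numeric(n)
  peaks <- seq(101, by = 50, length.out = 16)
  for (i in peaks) {
    accel[(i - 10):(i + 10)] <- 5 * sin(pi * (0:20) / 20)
    fsr[(i - 10):(i + 10)] <- 10
  }
  rec <- make_recording(accel, fsr)
  ph <- tibble::tibble(
    t_start = 0.5, t_stand_end = 1.0, t_turn_start = 4.74, t_turn_end = 5.26,
    t_walkback_end = 8.5, t_end = 9, tug_time = 8.5
  )
  steps <- detect_steps(rec, ph)
  gp <- gait_params(steps, rec, ph)
  walking <- gp$inst_cadence[[1]]
  expect_true(all(abs(walking - 120) < 1e-9))
  expect_equal(gp$cadence_mean, 120)
})

test_that("speed is accumulated stride length over walking time", {
  sim <- simulate_tug(gait_profile(cadence_cv = 0, stride_cv = 0), seed = 2)
  ph <- segment_tug(sim$recording)
  steps <- detect_steps(sim$recording, ph)
  gp <- gait_params(steps, sim$recording, ph)
  expect_equal(
    gp$speed,
    sum(gp$stride_lengths[[1]]) / (ph$t_walkback_end - ph$t_stand_end)
  )
})

test_that("the coefficient of variation matches a two-pass oracle to 1e-12", {
  expect_equal(coefficient_of_variation(rep(7, 10)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 50)
  set.seed(20)
  for (i in 1:5) {
    x <- abs(rnorm(sample(5:50, 1), 10, 2))
    expect_equal(coefficient_of_variation(x), oracle_cv(x), tolerance = 1e-12)
    expect_equal(
      coefficient_of_variation(3.7 * x),
      coefficient_of_variation(x),
      tolerance = 1e-12
    )
  }
  expect_error(coefficient_of_variation(c(1)), class = "solegait_error_parameter")
  expect_error(coefficient_of_variation(c(-1, 1)), class = "solegait_error_undefined")
})

test_that("the risk index follows its defining arithmetic", {
  gp <- tibble::tibble(
    n_steps = 10L, cadence_mean = 110, speed = 1.0,
    inst_cadence = list(c(100, 110, 120, 110, 100, 121)),
    stride_lengths = list(c(1, 1.1, 0.9, 1.05))
  )
  rk <- risk_of_falling(gp)
  expect_equal(rk$risk, rk$alpha * (rk$cv_cadence + rk$cv_stride))
  expect_equal(rk$alpha, 1)

  # regular gait scores zero risk
  gp0 <- gp
  gp0$inst_cadence <- list(rep(110, 6))
  gp0$stride_lengths <- list(rep(1, 4))
  expect_equal(risk_of_falling(gp0)$risk, 0)

  # doubling speed halves the risk
  gp2 <- gp
  gp2$speed <- 2.0
  expect_equal(risk_of_falling(gp2)$risk, rk$risk / 2)

  # alpha_c rescales linearly
  expect_equal(risk_of_falling(gp, alpha_c = 2)$risk, 2 * rk$risk)

  gp_bad <- gp
  gp_bad$speed <- 0
  expect_error(risk_of_falling(gp_bad), class = "solegait_error_parameter")
})

test_that("risk is monotone in each CV and antitone in speed over a grid", {
  risk_at <- function(cv_cad, cv_sl, speed) {
    base <- seq_len(20)
    cad <- 110 * (1 + cv_cad / 100 * scale(base)[, 1] / sd(scale(base)[, 1]))
    gp <- tibble::tibble(
      n_steps = 21L, cadence_mean = 110, speed = speed,
      inst_cadence = list(110 + (cad - 110)),
      stride_lengths = list(1 + cv_sl / 100 * scale(base)[, 1] / sd(scale(base)[, 1]))
    )
    risk_of_falling(gp)$risk
  }
  cvs <- c(1, 3, 5, 8, 12)
  speeds <- c(0.5, 1, 2)
  for (sp in speeds) {
    for (cv2 in cvs) {
      r <- vapply(cvs, risk_at, numeric(1), cv_sl = cv2, speed = sp)
      expect_true(all(diff(r) > 0))
      r2 <- vapply(cvs, function(c2) risk_at(cv2, c2, sp), numeric(1))
      expect_true(all(diff(r2) > 0))
    }
  }
  for (cv in cvs) {
    r <- vapply(speeds, function(sp) risk_at(cv, cv, sp), numeric(1))
    expect_true(all(diff(r) < 0))
  }
})

test_that("TUG times map onto the printed mobility categories", {
  mk <- function(tt) tibble::tibble(tug_time = tt)
  expect_equal(categorize_tug(mk(8)), "normal")
  expect_equal(categorize_tug(mk(17)), "increased_risk")
  expect_equal(categorize_tug(mk(10)), "intermediate")
  expect_equal(categorize_tug(mk(16)), "intermediate")
  expect_equal(categorize_tug(mk(9.999)), "normal")
  expect_equal(categorize_tug(mk(16.001)), "increased_risk")
})
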