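test_that("orientation handles canonical attitudes and gimbal lock", {
  n <- 300
  mk <- function(ax, ay, az) sensor_frame(
    time = (0:(n - 1)) / 10, depth = rep(5, n),
    accel = cbind(rep(ax, n), rep(ay, n), rep(az, n)),
    mag = cbind(rep(0.5, n), rep(0, n), rep(-0.86, n)), rate = 10)
  flat <- estimate_orientation(mk(0, 0, 1))
  expect_equal(mean(flat$pitch), 0, tolerance = 1e-6)
  expect_equal(mean(flat$roll), 0, tolerance = 1e-6)
  expect_false(any(flat$roll_undefined))

  vert <- estimate_orientation(mk(-1, 0, 0))
  expect_equal(mean(vert$pitch), 90, tolerance = 1e-6)
  expect_true(all(vert$roll_undefined))
})

test_that("pitch decomposition is exactly additive and recovers components", {
  rate <- 10
  tt <- (0:600) / rate
  ramp <- 20 * tt / max(tt)
  sine <- 6 * sin(2 * pi * 0.4 * tt)
  dec <- decompose_pitch(ramp + sine, rate)
  expect_equal(dec$body_pitch + dec$fluke_pitch, ramp + sine,
               tolerance = 1e-12)
  mid <- 100:500
  expect_lt(max(abs(dec$body_pitch[mid] - ramp[mid])), 2)
  expect_equal(max(abs(dec$fluke_pitch[mid])), 6, tolerance = 0.6)

  const <- decompose_pitch(rep(20, 200), rate)
  expect_equal(const$body_pitch, rep(20, 200), tolerance = 1e-4)
  expect_lt(max(abs(const$fluke_pitch)), 1e-3)
  expect_error(decompose_pitch(rep(1, 20), rate), "10 s")
})

test_that("orientation-corrected depth rate masks shallow pitch", {
  rate <- 10
  n <- 200
  # descending at a constant 2 m/s
  depth <- seq(0, by = 2 / rate, length.out = n)
  sp90 <- speed_from_depth_rate(depth * 1.5, rep(90, n), rate)
  expect_equal(stats::median(sp90$speed, na.rm = TRUE), 3, tolerance = 0.01)
  sp30 <- speed_from_depth_rate(depth, rep(31, n), rate)
  expect_equal(stats::median(sp30$speed, na.rm = TRUE), 2 / sin(31 * pi / 180),
               tolerance = 0.02)
  sp20 <- speed_from_depth_rate(depth, rep(20, n), rate)
  expect_true(all(is.na(sp20$speed)))
  expect_false(any(sp20$valid))
})

test_that("stroke counting handles whole, half, and fractional cycles", {
  rate <- 25
  seg <- function(dur) list(start = 1L, exit = as.integer(dur * rate) + 1L)
  tt <- function(dur) seq(0, dur, by = 1 / rate)

  full <- count_strokes(sin(2 * pi * 0.5 * tt(8)), seg(8), rate)
  expect_equal(full$n_strokes, 4)
  expect_equal(full$stroke_frequency, 0.5)

  half <- count_strokes(sin(2 * pi * 0.5 * tt(7)), seg(7), rate)
  expect_equal(half$n_strokes, 3.5)

  flat <- count_strokes(rep(0.01, 201), seg(8), rate)
  expect_equal(flat$n_strokes, 0)
  expect_equal(flat$stroke_frequency, 0)

  # trailing half-stroke beyond the last full cycle is dropped
  trail <- count_strokes(sin(2 * pi * 0.5 * tt(8.8)), seg(8.8), rate)
  expect_equal(trail$n_strokes, 4, tolerance = 0.01)

  # leading partial cycle enters as a fraction; the quarter-cycle tail
  # after the last zero is dropped
  lead <- count_strokes(sin(2 * pi * 0.5 * (tt(9) - 0.5)), seg(9), rate)
  expect_equal(lead$n_strokes, 4.25, tolerance = 0.05)

  expect_error(count_strokes(sin(tt(0.5)), seg(0.5), rate), "1 s")
})

test_that("jiggle calibration recovers the generator's speed law", {
  jig <- fixture_jiggle()
  expect_equal(jig$model$slope, 1.5, tolerance = 0.075) # within 5%
  expect_gt(jig$model$r_squared, 0.9)
  # round trip on the calibration data itself
  est <- speed_from_jiggle(jig$frame, jig$model)
  sel <- is.finite(jig$ref$speed) & jig$speed_true > 2 & jig$speed_true < 6.5
  expect_lt(stats::median(abs(est$speed[sel] / jig$speed_true[sel] - 1)), 0.05)
  # all-masked reference errors out
  expect_error(calibrate_jiggle_speed(jig$frame,
                                      rep(NA_real_, length(jig$frame))),
               "valid")
})

test_that("jiggle speeds are clamped and flagged outside calibration range", {
  jig <- fixture_jiggle()
  flat <- data.frame(time = seq(0, 10, by = 1 / 1600), depth = 5, speed = 0,
                     body_pitch = 0, fluke_pitch = 0, roll = 0, heading = 0,
                     fluking = FALSE)
  quiet <- synthesize_sensors(flat, rate = 400, noise_sd = 0, seed = 5,
                              jiggle_c = 0)
  est <- speed_from_jiggle(quiet, jig$model)
  expect_true(all(est$flagged))
  expect_equal(unique(est$speed), jig$model$speed_range[1])
  expect_error(speed_from_jiggle(quiet, jig$model, window = 60), "window")
})

test_that("depth-rate and jiggle speed methods agree where both are valid", {
  jig <- fixture_jiggle()
  est <- speed_from_jiggle(jig$frame, jig$model)
  sel <- is.finite(jig$ref$speed) & jig$speed_true > 2 & jig$speed_true < 6.5
  expect_lt(abs(mean(est$speed[sel]) /
                  mean(jig$ref$speed[sel], na.rm = TRUE) - 1), 0.10)
  expect_lt(stats::median(abs(est$speed[sel] / jig$ref$speed[sel] - 1),
                          na.rm = TRUE), 0.10)
})

test_that("breach detection finds fixtures with accurate starts", {
  dep <- fixture_deployment()
  expect_equal(nrow(dep$segments), 4)
  expect_lt(max(abs(dep$segments$start_time - dep$truth$start_time)), 1.25)
  expect_lt(max(abs(dep$segments$exit_time - dep$truth$exit_time)), 0.5)
  # V start sits at the direction change, well below the surface
  iv <- which(dep$truth$shape == "V")
  expect_gt(dep$segments$start_depth[iv], 5)
})

test_that("three-breach fixture recovers three segments within a second", {
  fr <- generate_fixture_deployment(3, shapes = c("U", "V", "I"), rate = 25,
                                    seed = 21)
  truth <- attr(fr, "truth")
  o <- estimate_orientation(fr)
  segs <- detect_breaches(fr, o)
  expect_equal(nrow(segs), 3)
  expect_lt(max(abs(segs$start_time - truth$start_time)), 1)
  expect_equal(truth$shape, c("U", "V", "I"))
})

test_that("trajectory classification matches the generated shapes", {
  dep <- fixture_deployment()
  cls <- vapply(seq_len(nrow(dep$segments)), function(i)
    classify_trajectory(dep$frame, dep$orientation, dep$segments[i, ]),
    character(1))
  expect_equal(cls, dep$truth$shape)
})

test_that("breach metrics recover ground truth within tolerances", {
  for (seed in c(7, 8)) {
    dep <- fixture_deployment(seed)
    expect_equal(nrow(dep$segments), 4)
    for (i in seq_len(nrow(dep$segments))) {
      m <- breach_metrics(dep$frame, dep$orientation, dep$segments[i, ],
                          body_length = 14)
      tr <- dep$truth[i, ]
      expect_equal(m$exit_speed, tr$exit_speed,
                   tolerance = 0.05 * tr$exit_speed)
      expect_equal(m$depth, tr$start_depth, tolerance = 0.5)
      expect_equal(m$exit_pitch, tr$exit_pitch, tolerance = 2)
      # stroke counts are compared on the truth-aligned segment: counting
      # is only well-posed when the window is the true powered ascent
      if (tr$segment_duration >= 4) {
        seg_t <- list(
          start = which.min(abs(dep$frame$time - tr$start_time)),
          exit = which.min(abs(dep$frame$time - tr$exit_time)))
        st <- count_strokes(dep$orientation$fluke_pitch, seg_t,
                            dep$frame$rate)
        expect_equal(st$n_strokes, tr$n_strokes, tolerance = 0.8)
      }
      expect_equal(m$speed_method, "depth_rate")
    }
  }
})

test_that("roll is undefined at steep exits and jiggle used at shallow ones", {
  p85 <- trajectory_params("I", 20, 6, 85, duration = 30, seed = 31)
  fr <- synthesize_sensors(simulate_breach_trajectory(p85, dt = 1 / 200),
                           rate = 25, noise_sd = 0, seed = 31)
  o <- estimate_orientation(fr)
  seg <- list(start = length(fr) - as.integer(6 * fr$rate),
              exit = length(fr),
              start_depth = 20)
  m <- breach_metrics(fr, o, seg, body_length = 14)
  expect_true(is.na(m$exit_roll))
  expect_gt(m$exit_pitch, 80)

  # shallow exit pitch routes through the jiggle model
  p23 <- trajectory_params("U", 2.5, 4, 23, duration = 25, seed = 32)
  tr23 <- simulate_breach_trajectory(p23, dt = 1 / 1600)
  fr23 <- synthesize_sensors(tr23, rate = 400, noise_sd = 0, seed = 32)
  o23 <- estimate_orientation(fr23)
  truth23 <- attr(tr23, "truth")
  seg23 <- list(start = which.min(abs(fr23$time - truth23$start_time)),
                exit = length(fr23), start_depth = 2.5)
  m23 <- breach_metrics(fr23, o23, seg23, body_length = 14,
                        jiggle_model = fixture_jiggle()$model)
  expect_equal(m23$speed_method, "jiggle")
  expect_warning(
    breach_metrics(fr23, o23, seg23, body_length = 14),
    "jiggle")
})

test_that("metrics are invariant to a uniform time shift", {
  dep <- fixture_deployment()
  fr <- dep$frame
  shifted <- sensor_frame(fr$time + 1000, fr$depth, fr$accel, fr$mag,
                          rate = fr$rate)
  o2 <- estimate_orientation(shifted)
  segs2 <- detect_breaches(shifted, o2)
  expect_equal(segs2$start, dep$segments$start)
  expect_equal(segs2$exit, dep$segments$exit)
  m1 <- breach_metrics(fr, dep$orientation, dep$segments[2, ], 14)
  m2 <- breach_metrics(shifted, o2, segs2[2, ], 14)
  expect_equal(m1$exit_speed, m2$exit_speed, tolerance = 1e-9)
  expect_equal(m1$n_strokes, m2$n_strokes, tolerance = 1e-9)
})
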