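test_that("trajectories end at the surface with the prescribed exit state", {
  shapes <- list(
    trajectory_params("U", 2.5, 4, 45, duration = 25, seed = 1),
    trajectory_params("V", 12, 6, 55, initial_speed = 1.5, duration = 40,
                      seed = 2),
    trajectory_params("I", 30, 7, 65, duration = 35, seed = 3),
    trajectory_params("J", 15, 4.5, 50, duration = 35, seed = 4)
  )
  for (p in shapes) {
    tr <- simulate_breach_trajectory(p)
    n <- nrow(tr)
    expect_equal(tr$depth[n], 0, tolerance = 1e-6)
    expect_equal(tr$speed[n], p$exit_speed, tolerance = 1e-6)
    expect_equal(tr$body_pitch[n] + tr$fluke_pitch[n], p$exit_pitch,
                 tolerance = 1e-6)
    expect_true(all(tr$depth >= 0))
    truth <- attr(tr, "truth")
    expect_lt(truth$start_time, truth$exit_time)
    expect_equal(truth$shape, p$shape)
  }
})

test_that("shape signatures are built as described", {
  # U: >= 2 s of near-horizontal travel before the final pitch-up
  u <- simulate_breach_trajectory(
    trajectory_params("U", 2.5, 4, 50, duration = 25, seed = 5))
  tu <- attr(u, "truth")
  pre <- u$time >= tu$start_time - 2.5 & u$time < tu$start_time
  expect_true(all(abs(u$body_pitch[pre]) < 20))
  expect_equal(u$depth[pre], rep(2.5, sum(pre)), tolerance = 1e-6)

  # V from the surface: single interior depth maximum at the named nadir
  v <- simulate_breach_trajectory(
    trajectory_params("V", 12, 5, 55, initial_speed = 1.5, duration = 40,
                      seed = 6))
  expect_equal(max(v$depth), 12, tolerance = 0.5)
  imax <- which.max(v$depth)
  expect_true(imax > 1 && imax < nrow(v))
  expect_lt(v$depth[1], 0.2)

  # impossible parameters error rather than silently failing to surface
  expect_error(simulate_breach_trajectory(
    trajectory_params("I", 300, 2.1, 40, initial_speed = 2,
                      duration = 30, seed = 7)), "duration|surface")
})

test_that("sensor synthesis renders gravity correctly and is deterministic", {
  flat <- data.frame(time = seq(0, 20, by = 1 / 100), depth = 5,
                     speed = 0, body_pitch = 0, fluke_pitch = 0, roll = 0,
                     heading = 10, fluking = FALSE)
  fr <- synthesize_sensors(flat, rate = 25, noise_sd = 0, seed = 1,
                           jiggle_c = 0)
  expect_equal(colMeans(fr$accel), c(0, 0, 1), tolerance = 1e-9)

  vert <- transform(flat, body_pitch = 90)
  fv <- synthesize_sensors(vert, rate = 25, noise_sd = 0, seed = 1,
                           jiggle_c = 0)
  expect_equal(mean(abs(fv$accel[, 1])), 1, tolerance = 1e-9)

  p <- trajectory_params("V", 10, 5, 50, initial_speed = 1.2, duration = 35,
                         seed = 9)
  tr <- simulate_breach_trajectory(p)
  a <- synthesize_sensors(tr, rate = 50, noise_sd = 0.02, seed = 42)
  b <- synthesize_sensors(tr, rate = 50, noise_sd = 0.02, seed = 42)
  expect_identical(a$accel, b$accel)
  expect_identical(a$mag, b$mag)
})

test_that("orientation estimation inverts zero-noise synthesis within 1-2 deg", {
  tilted <- data.frame(time = seq(0, 30, by = 1 / 100), depth = 5,
                       speed = 0, body_pitch = 45, fluke_pitch = 0,
                       roll = 30, heading = 70, fluking = FALSE)
  fr <- synthesize_sensors(tilted, rate = 25, noise_sd = 0, seed = 1,
                           jiggle_c = 0)
  o <- estimate_orientation(fr)
  mid <- 200:550
  expect_equal(mean(o$pitch[mid]), 45, tolerance = 1)
  expect_equal(mean(o$roll[mid]), 30, tolerance = 2)
  expect_equal(mean(o$heading[mid]), 70, tolerance = 2)
})

test_that("deployment generator meets its contract", {
  bg <- generate_fixture_deployment(0, rate = 25, seed = 1)
  expect_equal(nrow(attr(bg, "truth")), 0)
  o <- estimate_orientation(bg)
  expect_equal(nrow(detect_breaches(bg, o)), 0)

  dep <- fixture_deployment()
  expect_equal(attr(dep$frame, "truth")$shape, c("U", "V", "I", "J"))
  expect_true(all(diff(attr(dep$frame, "truth")$start_time) > 30))

  a <- generate_fixture_deployment(2, c("U", "V"), rate = 25, seed = 5)
  b <- generate_fixture_deployment(2, c("U", "V"), rate = 25, seed = 5)
  expect_identical(a$depth, b$depth)
  expect_identical(a$accel, b$accel)
})

test_that("rendered jiggle follows the generator's speed law", {
  jig <- fixture_jiggle()
  # held-out check: predict speeds on a second frame from the same law
  p <- trajectory_params("V", 20, 6.5, 55, initial_speed = 3.7,
                         duration = 30, stroke_frequency = 0.4, seed = 13)
  fr2 <- synthesize_sensors(simulate_breach_trajectory(p, dt = 1 / 1600),
                            rate = 400, noise_sd = 0, seed = 14)
  est <- speed_from_jiggle(fr2, jig$model)
  ts <- attr(fr2, "speed_true")
  const <- which(abs(ts - 3.7) < 0.01)
  expect_equal(mean(est$speed[const]), 3.7, tolerance = 0.05 * 3.7)
})
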