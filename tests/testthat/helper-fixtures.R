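# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# standard 4-shape deployment with noise, plus orientation and detections
fixture_deployment <- function(seed = 7) {
  cached(paste0("dep", seed), {
    fr <- generate_fixture_deployment(4, shapes = c("U", "V", "I", "J"),
                                      rate = 25, seed = seed)
    o <- estimate_orientation(fr)
    list(frame = fr, orientation = o,
         segments = detect_breaches(fr, o),
         truth = attr(fr, "truth"))
  })
}

# clean 400 Hz single-breach frame for jiggle work
fixture_jiggle <- function() {
  cached("jig", {
    p <- trajectory_params("V", start_depth = 25, exit_speed = 7,
                           exit_pitch = 60, initial_speed = 1.5,
                           duration = 45, stroke_frequency = 0.4, seed = 11)
    fr <- synthesize_sensors(simulate_breach_trajectory(p, dt = 1 / 1600),
                             rate = 400, noise_sd = 0, seed = 12)
    o <- estimate_orientation(fr)
    ref <- speed_from_depth_rate(fr$depth, o$body_pitch, fr$rate)
    list(frame = fr, orientation = o, ref = ref,
         model = calibrate_jiggle_speed(fr, ref$speed),
         speed_true = attr(fr, "speed_true"))
  })
}

# trapezoid quadrature of the drag-power integral over a linear ramp:
# the independent oracle for the closed-form acceleration drag work
drag_work_quadrature <- function(morph, profile, coeffs = hydro_coefficients(),
                                 dt = 1e-3) {
  tt <- seq(0, profile$T_acc, by = dt)
  U <- profile$U_i + (profile$U_f - profile$U_i) * tt / profile$T_acc
  Re <- morph$L_body * U / coeffs$nu
  shape <- 1 + 1.5 * (morph$w_max / morph$L_body)^1.5 +
    7 * (morph$w_max / morph$L_body)^3
  P <- coeffs$gamma * coeffs$F_amp * 0.5 * coeffs$rho_w *
    0.08 * morph$M_body^0.65 * (0.072 / Re^0.2) * shape * U^3
  fric <- sum((utils::head(P, -1) + utils::tail(P, -1)) / 2) * dt
  fric + 0.5 * coeffs$k * morph$M_body * (profile$U_f^2 - profile$U_i^2)
}

whale1 <- function() morphometry("humpback", L_body = 7.8, M_body = 7000)
whale1_profile <- function() speed_profile(1.75, 6.2, 8.0)
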