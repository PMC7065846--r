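# Ground-truthed synthetic deployments: U/V/I/J breach trajectories rendered
# into depth + accelerometer + magnetometer streams, so every pipeline stage
# can be tested against known kinematics.

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  force(code)
}

#' Parameters of one synthetic breach trajectory
#'
#' @param shape Trajectory shape: `"U"` (near-surface horizontal run, late
#'   pitch-up), `"V"` (surface dive then abrupt upward turn), `"I"`
#'   (station-hold at depth, direct ascent), or `"J"` (slow unpowered
#'   ascent, then burst).
#' @param start_depth Depth (m) at the start of the breaching acceleration
#'   (run depth for U, nadir for V, hold depth for I, burst depth for J).
#' @param exit_speed Along-path speed at the surface (m/s), > `initial_speed`.
#' @param exit_pitch Exit pitch in degrees, (0, 90].
#' @param exit_roll Exit roll in degrees (0 = upright; nonzero fixtures ramp
#'   the roll in linearly over the final second).
#' @param stroke_frequency Fluke-stroke frequency in Hz.
#' @param initial_speed Speed at the start of the acceleration (m/s).
#' @param duration Total record length in s; the exit is the final sample.
#' @param seed Integer seed recorded into the ground truth.
#' @param stroke_amplitude Fluke pitch oscillation amplitude in degrees.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(shape = c("U", "V", "I", "J"), start_depth,
                              exit_speed, exit_pitch, exit_roll = 0,
                              stroke_frequency = 0.4, initial_speed = 1,
                              duration = 30, seed = 1L,
                              stroke_amplitude = 8) {
  shape <- match.arg(shape)
  if (exit_speed <= initial_speed || initial_speed < 0)
    stop("need exit_speed > initial_speed >= 0")
  if (exit_pitch <= 0 || exit_pitch > 90)
    stop("exit_pitch must be in (0, 90] degrees")
  if (duration <= 0) stop("duration must be positive")
  if (start_depth <= 0) stop("start_depth must be positive")
  if (stroke_frequency <= 0) stop("stroke_frequency must be positive")
  structure(list(shape = shape, start_depth = start_depth,
                 exit_speed = exit_speed, exit_pitch = exit_pitch,
                 exit_roll = exit_roll, stroke_frequency = stroke_frequency,
                 initial_speed = initial_speed, duration = duration,
                 seed = as.integer(seed), stroke_amplitude = stroke_amplitude),
            class = "trajectory_params")
}

# ascent duration for a ramped speed Ui->Uf at pitch profile theta(t):
# solves  integral( U(t) sin(theta(t)) ) dt = depth  for T_a by bisection
solve_ascent_duration <- function(depth, Ui, Uf, pitch_fun, lo = 0.5, hi = 300) {
  vert <- function(Ta) {
    t <- seq(0, Ta, length.out = 400L)
    U <- Ui + (Uf - Ui) * t / Ta
    v <- U * sin(pitch_fun(t, Ta) * pi / 180)
    sum((utils::head(v, -1) + utils::tail(v, -1)) / 2) * (t[2] - t[1]) - depth
  }
  if (vert(hi) < 0) stop("ascent cannot reach the surface: parameters too slow")
  stats::uniroot(vert, c(lo, hi), tol = 1e-8)$root
}

# assemble phase tables into one trajectory data frame on a fine grid
build_trajectory <- function(phases, dt) {
  t_end <- sum(vapply(phases, function(p) p$dur, 0))
  tt <- seq(0, t_end, by = dt)
  n <- length(tt)
  out <- data.frame(time = tt, depth = NA_real_, speed = NA_real_,
                    body_pitch = NA_real_, fluking = FALSE)
  t0 <- 0
  for (p in phases) {
    idx <- which(tt >= t0 - dt / 2 & tt <= t0 + p$dur + dt / 2)
    tl <- tt[idx] - t0
    out$depth[idx] <- p$depth(tl)
    out$speed[idx] <- p$speed(tl)
    out$body_pitch[idx] <- p$pitch(tl)
    out$fluking[idx] <- p$fluking
    t0 <- t0 + p$dur
  }
  out
}

#' Simulate the continuous kinematic state of one breach
#'
#' Builds depth, along-path speed, body pitch, fluke pitch, roll, and
#' heading versus time on a fine grid for the requested trajectory shape.
#' The final sample is the water exit: depth exactly 0, speed exactly
#' `exit_speed`, body pitch exactly `exit_pitch` (the fluke oscillation is
#' tapered out over the final 0.4 s). Ground truth (start time/depth, exit
#' state, stroke count, shape) is attached as attribute `"truth"`.
#'
#' @param params A [trajectory_params()].
#' @param dt Fine-grid time step in s (default 1/800).
#' @return A data frame with columns `time`, `depth`, `speed`,
#'   `body_pitch`, `fluke_pitch`, `roll`, `heading`, `fluking`, plus a
#'   `"truth"` attribute (one-row data frame).
#' @export
simulate_breach_trajectory <- function(params, dt = 1 / 800) {
  stopifnot(inherits(params, "trajectory_params"))
  p <- params
  th_e <- p$exit_pitch
  d0 <- p$start_depth
  Ui <- p$initial_speed
  Uf <- p$exit_speed

  ramp <- function(a, b, frac) a + (b - a) * pmin(pmax(frac, 0), 1)

  phases <- list()
  if (p$shape == "U") {
    # horizontal run at shallow depth, then a late pitch-up at full speed
    run_pitch <- -2
    dth <- (th_e - run_pitch) * pi / 180
    # vertical distance over a linear pitch ramp at constant speed Uf
    T_p <- d0 * dth / (Uf * (cos(run_pitch * pi / 180) - cos(th_e * pi / 180)))
    T_run <- 6
    T_pre <- p$duration - T_run - T_p
    if (T_pre < 0.5)
      stop("duration too short for the U-shape run and pitch-up")
    phases <- list(
      list(dur = T_pre, depth = function(t) rep(d0, length(t)),
           speed = function(t) rep(Ui, length(t)),
           pitch = function(t) rep(run_pitch, length(t)), fluking = FALSE),
      list(dur = T_run, depth = function(t) rep(d0, length(t)),
           speed = function(t) ramp(Ui, Uf, t / T_run),
           pitch = function(t) rep(run_pitch, length(t)), fluking = TRUE),
      list(dur = T_p,
           depth = function(t) {
             th <- ramp(run_pitch, th_e, t / T_p) * pi / 180
             # analytic integral of Uf sin(theta(t)) for the linear ramp
             d0 - Uf * T_p / dth * (cos(run_pitch * pi / 180) - cos(th))
           },
           speed = function(t) rep(Uf, length(t)),
           pitch = function(t) ramp(run_pitch, th_e, t / T_p), fluking = TRUE)
    )
    t_start <- T_pre + T_run
    seg_dur <- T_p
  } else if (p$shape == "V") {
    # glide down from the surface, abrupt upward turn at the nadir
    if (Ui < 0.3) stop("V-shape needs initial_speed >= 0.3 m/s to descend")
    th_d <- 45
    T_d <- (d0 - 0.05) / (Ui * sin(th_d * pi / 180))
    pitch_fun <- function(t, Ta) ramp(-th_d, th_e, t / min(1, Ta / 2))
    T_a <- solve_ascent_duration(d0, Ui, Uf, pitch_fun)
    T_pre <- p$duration - T_d - T_a
    if (T_pre < 0.5) stop("duration too short for the V-shape dive and ascent")
    asc <- ascent_phase(d0, Ui, Uf, th_e, T_a, pitch_fun, dt)
    phases <- list(
      list(dur = T_pre, depth = function(t) rep(0.05, length(t)),
           speed = function(t) rep(Ui, length(t)),
           pitch = function(t) rep(0, length(t)), fluking = FALSE),
      list(dur = T_d, depth = function(t) 0.05 + Ui * sin(th_d * pi / 180) * t,
           speed = function(t) rep(Ui, length(t)),
           pitch = function(t) rep(-th_d, length(t)), fluking = FALSE),
      asc
    )
    t_start <- T_pre + T_d
    seg_dur <- T_a
  } else if (p$shape == "I") {
    # motionless station-hold at depth, then a direct powered ascent
    pitch_fun <- function(t, Ta) ramp(0, th_e, t / min(0.7, Ta / 2))
    T_a <- solve_ascent_duration(d0, Ui, Uf, pitch_fun)
    T_pre <- p$duration - T_a
    if (T_pre < 0.5) stop("duration too short for the I-shape ascent")
    asc <- ascent_phase(d0, Ui, Uf, th_e, T_a, pitch_fun, dt)
    phases <- list(
      list(dur = T_pre, depth = function(t) rep(d0, length(t)),
           speed = function(t) rep(0, length(t)),
           pitch = function(t) rep(0, length(t)), fluking = FALSE),
      asc
    )
    t_start <- T_pre
    seg_dur <- T_a
  } else { # J
    # slow unpowered ascent (0.4 m/s vertical at 12 deg), then the burst
    v_slow <- 0.4
    th_slow <- 12
    T_slow <- 8
    d_deep <- d0 + v_slow * T_slow
    pitch_fun <- function(t, Ta) ramp(th_slow, th_e, t / min(0.7, Ta / 2))
    T_a <- solve_ascent_duration(d0, Ui, Uf, pitch_fun)
    T_pre <- p$duration - T_slow - T_a
    if (T_pre < 0.5) stop("duration too short for the J-shape ascent")
    asc <- ascent_phase(d0, Ui, Uf, th_e, T_a, pitch_fun, dt)
    phases <- list(
      list(dur = T_pre, depth = function(t) rep(d_deep, length(t)),
           speed = function(t) rep(0, length(t)),
           pitch = function(t) rep(0, length(t)), fluking = FALSE),
      list(dur = T_slow, depth = function(t) d_deep - v_slow * t,
           speed = function(t) rep(v_slow / sin(th_slow * pi / 180), length(t)),
           pitch = function(t) rep(th_slow, length(t)), fluking = FALSE),
      asc
    )
    t_start <- T_pre + T_slow
    seg_dur <- T_a
  }

  traj <- build_trajectory(phases, dt)
  n <- nrow(traj)
  # exact exit state on the final sample
  traj$depth[n] <- 0
  traj$speed[n] <- Uf
  traj$body_pitch[n] <- th_e
  traj$depth <- pmax(traj$depth, 0)

  # fluke-stroke oscillation, phase-anchored at the segment start, tapered
  # to zero over the final 0.4 s so the exit pitch is exact
  taper <- pmin(1, pmax(0, (traj$time[n] - traj$time) / 0.4))
  traj$fluke_pitch <- ifelse(
    traj$fluking,
    p$stroke_amplitude * taper *
      sin(2 * pi * p$stroke_frequency * (traj$time - t_start)),
    0
  )

  # roll: upright except an optional linear ramp over the final second
  traj$roll <- if (p$exit_roll != 0) {
    pmax(0, 1 - (traj$time[n] - traj$time)) * p$exit_roll
  } else rep(0, n)
  traj$heading <- rep(with_seed(p$seed, stats::runif(1, 0, 360)), n)

  attr(traj, "params") <- p
  attr(traj, "truth") <- data.frame(
    start_time = t_start, start_depth = d0, exit_time = traj$time[n],
    exit_speed = Uf, exit_pitch = th_e, exit_roll = p$exit_roll,
    n_strokes = p$stroke_frequency * seg_dur, segment_duration = seg_dur,
    shape = p$shape, seed = p$seed, stringsAsFactors = FALSE
  )
  traj
}

# powered-ascent phase: linear speed ramp, pitch profile pitch_fun, depth
# from the numerically integrated vertical speed rescaled to end exactly at 0
ascent_phase <- function(d0, Ui, Uf, th_e, T_a, pitch_fun, dt) {
  tg <- seq(0, T_a, by = min(dt, T_a / 400))
  Ug <- Ui + (Uf - Ui) * tg / T_a
  vg <- Ug * sin(pitch_fun(tg, T_a) * pi / 180)
  cum <- c(0, cumsum((utils::head(vg, -1) + utils::tail(vg, -1)) / 2 *
                       diff(tg)))
  scale <- d0 / cum[length(cum)]
  depth_fun <- stats::approxfun(tg, d0 - cum * scale, rule = 2)
  list(dur = T_a,
       depth = depth_fun,
       speed = function(t) Ui + (Uf - Ui) * pmin(t, T_a) / T_a,
       pitch = function(t) pitch_fun(pmin(t, T_a), T_a),
       fluking = TRUE)
}

# band-limited vibration carrier with unit global RMS (one column per axis)
jiggle_carrier <- function(n, rate, band) {
  hi <- min(band[2], 0.45 * rate)
  bf <- signal::butter(4, c(band[1], hi) / (rate / 2), type = "pass")
  sapply(1:3, function(j) {
    w <- stats::rnorm(n + 200)
    y <- as.numeric(signal::filter(bf, w))[-(1:200)]
    y / sqrt(mean(y^2))
  })
}

#' Render a trajectory into a sensor frame
#'
#' Samples the trajectory at `rate` and synthesizes the sensors under the
#' quasi-static assumption: acceleration is the gravity vector rotated into
#' the animal frame by pitch and roll, `(-sin p, cos p sin r, cos p cos r)`
#' in g; magnetics are a fixed Earth vector (inclination
#' `mag_inclination`) rotated by heading, pitch, and roll. A band-limited
#' (10-45 Hz) vibration ("jiggle") whose RMS follows
#' `jiggle_c * speed^jiggle_exp` is split equally across the three axes,
#' emulating the speed-dependent flow noise that the jiggle speed method
#' calibrates against; it is only rendered when the rate can represent the
#' band (rate > 2 * band floor). White measurement noise `noise_sd` is
#' added to every accelerometer axis.
#'
#' @param traj Output of [simulate_breach_trajectory()] (or any data frame
#'   with the same columns sampled finer than `rate`).
#' @param rate Output sampling rate in Hz.
#' @param noise_sd Accelerometer white-noise standard deviation in g.
#' @param seed Integer seed; identical seeds give bit-identical frames.
#' @param jiggle_c,jiggle_exp Coefficient (g at 1 m/s) and exponent of the
#'   vibration-RMS versus speed law.
#' @param mag_inclination Magnetic inclination in degrees.
#' @return A [sensor_frame()] with the trajectory's `"truth"` attribute
#'   carried over.
#' @export
synthesize_sensors <- function(traj, rate, noise_sd = 0.02, seed = 1L,
                               jiggle_c = 0.02, jiggle_exp = 1.5,
                               mag_inclination = 60) {
  p <- attr(traj, "params")
  if (!is.null(p) && rate <= 2 * p$stroke_frequency)
    stop("rate must exceed twice the stroke frequency (aliasing)")
  dt_in <- stats::median(diff(traj$time))
  if (dt_in > 1 / rate)
    stop("trajectory must be sampled finer than the sensor rate")
  tt <- seq(traj$time[1], traj$time[nrow(traj)], by = 1 / rate)
  at <- function(col) stats::approx(traj$time, traj[[col]], tt, rule = 2)$y

  depth <- at("depth")
  speed <- at("speed")
  pitch <- (at("body_pitch") + at("fluke_pitch")) * pi / 180
  roll <- at("roll") * pi / 180
  head_ <- at("heading") * pi / 180
  n <- length(tt)

  accel <- cbind(-sin(pitch), cos(pitch) * sin(roll), cos(pitch) * cos(roll))

  # magnetics: world field (cos d, 0, -sin d) seen in the body frame
  d <- mag_inclination * pi / 180
  mw <- c(cos(d), 0, -sin(d))
  # v_body = Rx(-roll) Ry(-pitch) Rz(-heading) v_world
  m1 <- cos(head_) * mw[1]              # Rz(-psi): x
  m2 <- -sin(head_) * mw[1]             #           y
  m3 <- rep(mw[3], n)
  x2 <- cos(pitch) * m1 - sin(pitch) * m3   # Ry(-theta)
  z2 <- sin(pitch) * m1 + cos(pitch) * m3
  my <- cos(roll) * m2 + sin(roll) * z2     # Rx(-phi)
  mz <- -sin(roll) * m2 + cos(roll) * z2
  mag <- cbind(x2, my, mz)

  with_seed(seed, {
    # vibration band needs headroom above its 10 Hz floor to be rendered
    if (jiggle_c > 0 && 0.45 * rate > 12) {
      car <- jiggle_carrier(n, rate, c(10, 45))
      amp <- jiggle_c * speed^jiggle_exp / sqrt(3)
      accel <- accel + car * amp
    }
    if (noise_sd > 0) {
      accel <- accel + matrix(stats::rnorm(3L * n, sd = noise_sd), ncol = 3L)
      mag <- mag + matrix(stats::rnorm(3L * n, sd = 0.005), ncol = 3L)
    }
  })

  fr <- sensor_frame(time = tt, depth = depth, accel = accel, mag = mag,
                     rate = rate)
  attr(fr, "truth") <- attr(traj, "truth")
  attr(fr, "speed_true") <- speed
  fr
}

# background shallow-diving block: surface rest, one gentle dive, surface
background_block <- function(dur = 35, dive_depth = 4, dt = 1 / 50) {
  t_surf <- 5
  t_dive <- dur - 2 * t_surf
  depth_fun <- function(t) {
    d <- rep(0.05, length(t))
    in_dive <- t > t_surf & t < t_surf + t_dive
    d[in_dive] <- 0.05 + (dive_depth - 0.05) *
      sin(pi * (t[in_dive] - t_surf) / t_dive)^2
    d
  }
  tt <- seq(0, dur, by = dt)
  dep <- depth_fun(tt)
  v <- c(0, diff(dep)) / dt
  U_bg <- 1.5
  pitch <- -asin(pmin(pmax(v / U_bg, -0.95), 0.95)) * 180 / pi
  data.frame(time = tt, depth = dep, speed = U_bg, body_pitch = pitch,
             fluke_pitch = 3 * sin(2 * pi * 0.35 * tt) *
               as.numeric(dep > 0.5),
             roll = 0, heading = 0, fluking = FALSE)
}

# cosine blend between two depths (transit segment), pitch from depth rate
blend_block <- function(d_from, d_to, dt = 1 / 50, U = 1.5) {
  dur <- max(3, abs(d_to - d_from) / 0.8)
  tt <- seq(0, dur, by = dt)
  dep <- d_from + (d_to - d_from) * (1 - cos(pi * tt / dur)) / 2
  v <- c(0, diff(dep)) / dt
  pitch <- -asin(pmin(pmax(v / U, -0.95), 0.95)) * 180 / pi
  data.frame(time = tt, depth = dep, speed = U, body_pitch = pitch,
             fluke_pitch = 0, roll = 0, heading = 0, fluking = FALSE)
}

# post-exit block: short aerial phase holding the exit attitude, splashdown
aerial_block <- function(exit_pitch, exit_roll, dt = 1 / 50) {
  tt <- seq(0, 3, by = dt)
  dep <- ifelse(tt < 1.5, 0, pmin(0.3, (tt - 1.5) * 0.6))
  pitch <- ifelse(tt < 1.5, exit_pitch, pmax(-10, exit_pitch - (tt - 1.5) * 60))
  data.frame(time = tt, depth = dep, speed = 0.5, body_pitch = pitch,
             fluke_pitch = 0, roll = ifelse(tt < 1.5, exit_roll, 0),
             heading = 0, fluking = FALSE)
}

# draw per-shape parameters inside the envelopes seen in tagged humpbacks
draw_breach_params <- function(shape, seed) {
  with_seed(seed, {
    d0 <- switch(shape,
      U = stats::runif(1, 2.0, 2.8),
      V = stats::runif(1, 8, 16),
      I = stats::runif(1, 12, 30),
      J = stats::runif(1, 10, 25))
    Uf <- switch(shape,
      U = stats::runif(1, 2.8, 5),
      V = stats::runif(1, 3.5, 7),
      I = stats::runif(1, 3.5, 7.5),
      J = stats::runif(1, 3, 6))
    trajectory_params(
      shape = shape, start_depth = d0, exit_speed = Uf,
      exit_pitch = stats::runif(1, 38, 72),
      exit_roll = if (stats::runif(1) < 0.3) stats::runif(1, 90, 178) else 0,
      stroke_frequency = stats::runif(1, 0.3, 0.6),
      initial_speed = stats::runif(1, if (shape == "V") 1.2 else 0.8,
                                   min(1.8, Uf - 1)),
      duration = switch(shape, U = 25, V = 40, I = 30, J = 35),
      seed = seed)
  })
}

#' Generate a full synthetic deployment with ground truth
#'
#' Concatenates background shallow-diving blocks with `n_breaches` breach
#' trajectories (shapes cycled from `shapes`, parameters drawn per shape
#' from the envelopes observed in tagged humpback whales), separated by at
#' least 30 s of background behavior, and renders the whole record into
#' one sensor frame.
#'
#' @param n_breaches Number of breaches (>= 0).
#' @param shapes Character vector of shapes to cycle through.
#' @param rate Sensor rate in Hz (default 25).
#' @param seed Integer seed; drives parameter draws and sensor noise.
#' @param noise_sd Accelerometer noise in g.
#' @param params_list Optional list of [trajectory_params()] overriding the
#'   random draws (length `n_breaches`).
#' @return A [sensor_frame()] with attribute `"truth"`: a data frame with
#'   one row per breach (deployment-clock times).
#' @export
generate_fixture_deployment <- function(n_breaches, shapes = c("U", "V", "I", "J"),
                                        rate = 25, seed = 1L, noise_sd = 0.02,
                                        params_list = NULL) {
  if (n_breaches < 0) stop("n_breaches must be >= 0")
  dt <- 1 / max(2 * rate, 100)
  cols <- c("time", "depth", "speed", "body_pitch", "fluke_pitch", "roll",
            "heading", "fluking")
  segs <- list()
  truths <- list()
  clock <- 0
  append_seg <- function(s) {
    s$time <- s$time - s$time[1] + clock
    segs[[length(segs) + 1L]] <<- s[, cols]
    clock <<- utils::tail(s$time, 1) + dt
  }
  append_seg(background_block(dt = dt))
  if (n_breaches > 0) {
    shapes <- rep_len(shapes, n_breaches)
    for (i in seq_len(n_breaches)) {
      p <- if (!is.null(params_list)) params_list[[i]] else
        draw_breach_params(shapes[i], seed * 1000L + i)
      traj <- simulate_breach_trajectory(p, dt = dt)
      tr <- attr(traj, "truth")
      # keep only enough of the trajectory's own pre-phase to preserve the
      # classification signature; the deployment supplies earlier context
      keep_from <- max(0, tr$start_time - pre_context(p$shape))
      traj <- traj[traj$time >= keep_from - dt / 2, ]
      rel_start <- tr$start_time - keep_from
      rel_exit <- tr$exit_time - keep_from
      prev_depth <- utils::tail(segs[[length(segs)]]$depth, 1)
      append_seg(blend_block(prev_depth, traj$depth[1], dt = dt))
      breach_t0 <- clock
      append_seg(traj)
      tr$start_time <- breach_t0 + rel_start
      tr$exit_time <- breach_t0 + rel_exit
      truths[[i]] <- tr
      append_seg(aerial_block(p$exit_pitch, p$exit_roll, dt = dt))
      append_seg(background_block(dt = dt))
    }
  }
  big <- do.call(rbind, segs)
  big$time <- seq(0, by = dt, length.out = nrow(big)) # exact uniform grid
  big$heading <- 40 # constant deployment heading
  attr(big, "params") <- list(stroke_frequency = 0.3)
  fr <- synthesize_sensors(big, rate = rate, noise_sd = noise_sd, seed = seed)
  attr(fr, "truth") <- if (n_breaches > 0) do.call(rbind, truths) else
    data.frame()
  fr
}

# pre-breach context kept from the trajectory's own record, per shape:
# enough to preserve the classification signature
pre_context <- function(shape) switch(shape, U = 10, V = 30, I = 8, J = 12)

#' Write a ground-truth table as CSV
#'
#' @param truth The `"truth"` attribute of a generated deployment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
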