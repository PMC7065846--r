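# Tag-processing pipeline: sensor frame -> orientation -> speed -> breach
# segments -> per-breach metrics.

#' Default kinematic-processing configuration
#'
#' Every threshold used by the pipeline, overridable per call or via a
#' YAML run configuration. Values with an established provenance keep it:
#' 1 Hz sensor smoothing, 0.2 Hz body/fluke pitch split, 30 deg minimum
#' pitch for orientation-corrected depth rate, 80 deg gimbal-lock limit
#' for roll, 0.1 m surface threshold, 40% full-breach emergence cutoff.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of configuration values.
#' @export
kin_config <- function(...) {
  cfg <- list(
    sensor_lp_hz = 1,          # accel/mag smoothing before orientation
    pitch_split_hz = 0.2,      # body vs fluke pitch cutoff
    filter_order = 2,          # Butterworth order (applied fwd-bwd)
    surface_depth = 0.1,       # m; at or above this the tag is "at surface"
    min_pitch_speed = 30,      # deg; depth-rate speed valid above this
    gimbal_pitch = 80,         # deg; roll undefined at or above this
    min_ascent_speed = 0.8,    # m/s vertical, averaged over ascent_window
    ascent_window = 2,         # s before a surfacing
    fluke_rms_window = 2,      # s; sliding RMS of fluke pitch
    fluke_intensify_factor = 2,# x the 20th-percentile deployment RMS
    fluke_rms_quantile = 0.2,
    fluke_local_fraction = 0.5,# onset also clears this fraction of the
                               # burst's own RMS level (leakage guard)
    fluke_quiet_level = 2,     # deg RMS; "not fluking" ceiling for J
    search_back = 60,          # s; how far before an exit to look for a start
    context_window = 16,       # s of pre-start context for classification
    class_U_max_depth = 5,     # m
    class_U_flat_pitch = 20,   # deg
    class_U_flat_s = 2,        # s
    class_V_min_descent = 3,   # m
    class_V_lookback = 30,     # s since a surfacing
    class_I_max_rate = 0.3,    # m/s
    class_I_min_depth = 5,     # m
    class_IJ_quiet_s = 5,      # s of pre-ascent signature
    class_J_max_rate = 0.5,    # m/s upward
    class_J_min_rate = 0.05,   # m/s upward
    jiggle_band = c(10, 45),   # Hz
    jiggle_window = 1,         # s
    full_breach_threshold = 0.4,
    emergence_cap = 1.2,
    g = 9.81
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Estimate pitch, roll, and heading from a sensor frame
#'
#' Accelerometer and magnetometer channels are zero-lag low-pass filtered
#' (1 Hz) to remove fluke-stroke-scale vibration, then the quasi-static
#' orientation is computed: pitch is the arcsine of the (negated) surge
#' specific force over the acceleration norm, roll comes from the
#' sway/heave components, heading from the tilt-corrected magnetics. The
#' pitch signal is then split at 0.2 Hz into body pitch (low-pass) and
#' fluke pitch (residual), so the two components sum to the pitch exactly.
#' Roll is flagged undefined wherever |pitch| exceeds the gimbal-lock
#' limit (80 deg); samples with near-zero acceleration norm are flagged
#' undefined everywhere.
#'
#' @param frame A [sensor_frame()].
#' @param config A [kin_config()].
#' @return An `orientation_series` list: `pitch`, `roll`, `heading`,
#'   `body_pitch`, `fluke_pitch` (degrees), logical `roll_undefined` and
#'   `undefined`, and `rate`.
#' @export
estimate_orientation <- function(frame, config = kin_config()) {
  validate_sensor_frame(frame)
  rate <- frame$rate
  smooth <- function(m) {
    if (config$sensor_lp_hz < rate / 2) {
      apply(m, 2, zero_lag_lowpass, cutoff = config$sensor_lp_hz,
            rate = rate, order = config$filter_order)
    } else m
  }
  a <- smooth(frame$accel)
  m <- smooth(frame$mag)
  nrm <- sqrt(rowSums(a^2))
  undef <- nrm < 0.2
  nrm[undef] <- NA_real_
  pitch <- asin(pmin(pmax(-a[, 1] / nrm, -1), 1)) * 180 / pi
  roll <- atan2(a[, 2], a[, 3]) * 180 / pi
  roll_undef <- undef | abs(pitch) >= config$gimbal_pitch
  # tilt correction: rotate magnetics back through roll then pitch
  pr <- pitch * pi / 180
  rr <- roll * pi / 180
  y1 <- cos(rr) * m[, 2] - sin(rr) * m[, 3]
  z1 <- sin(rr) * m[, 2] + cos(rr) * m[, 3]
  w1 <- cos(pr) * m[, 1] + sin(pr) * z1
  heading <- (atan2(-y1, w1) * 180 / pi) %% 360
  dec <- decompose_pitch(pitch, rate, config)
  structure(list(pitch = pitch, roll = roll, heading = heading,
                 body_pitch = dec$body_pitch, fluke_pitch = dec$fluke_pitch,
                 roll_undefined = roll_undef, undefined = undef, rate = rate),
            class = "orientation_series")
}

#' Split pitch into body and fluke components
#'
#' Body pitch is the zero-lag low-pass of the pitch signal at the split
#' cutoff (0.2 Hz); fluke pitch is the residual, so
#' `body_pitch + fluke_pitch == pitch` exactly.
#'
#' @param pitch Pitch series in degrees.
#' @param rate Sampling rate in Hz.
#' @param config A [kin_config()].
#' @return List with `body_pitch` and `fluke_pitch`.
#' @export
decompose_pitch <- function(pitch, rate, config = kin_config()) {
  if (length(pitch) < 10 * rate)
    stop("need at least 10 s of data to split body and fluke pitch")
  body <- zero_lag_lowpass(pitch, config$pitch_split_hz, rate,
                           config$filter_order)
  list(body_pitch = body, fluke_pitch = pitch - body)
}

# centered derivative of a (pre-smoothed) series
deriv_center <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

# smoothed depth rate (m/s, positive down)
depth_rate <- function(frame, config = kin_config()) {
  d <- if (config$sensor_lp_hz < frame$rate / 2)
    zero_lag_lowpass(frame$depth, config$sensor_lp_hz, frame$rate,
                     config$filter_order) else frame$depth
  deriv_center(d, frame$rate)
}

#' Swim speed from orientation-corrected depth rate
#'
#' `speed = |d(depth)/dt| / |sin(pitch)|`, valid only where
#' |pitch| > `min_pitch` (default 30 deg): near-horizontal swimming has no
#' depth signature, so those samples are masked rather than estimated.
#'
#' @param depth Depth series (m) or a [sensor_frame()].
#' @param pitch Pitch series in degrees (ignored when `depth` is a frame
#'   and `orientation` given).
#' @param rate Sampling rate in Hz.
#' @param min_pitch Validity threshold in degrees.
#' @param config A [kin_config()] (for the smoothing cutoff).
#' @return List: `speed` (m/s, `NA` where masked) and logical `valid`.
#' @export
speed_from_depth_rate <- function(depth, pitch, rate,
                                  min_pitch = 30, config = kin_config()) {
  if (inherits(depth, "sensor_frame")) {
    rate <- depth$rate
    depth <- depth$depth
  }
  d <- if (config$sensor_lp_hz < rate / 2)
    zero_lag_lowpass(depth, config$sensor_lp_hz, rate, config$filter_order)
    else depth
  v <- deriv_center(d, rate)
  valid <- abs(pitch) > min_pitch & !is.na(pitch)
  speed <- ifelse(valid, abs(v) / abs(sin(pitch * pi / 180)), NA_real_)
  list(speed = speed, valid = valid)
}

# sliding-window RMS of the band-passed 3-axis acceleration energy
jiggle_rms <- function(frame, band = c(10, 45), window = 1) {
  rate <- frame$rate
  if (band[1] >= rate / 2)
    stop("jiggle band lies above Nyquist for this frame")
  hi <- min(band[2], 0.45 * rate)
  bp <- function(x) {
    h <- x - zero_lag_lowpass(x, band[1], rate)
    if (hi < 0.48 * rate) zero_lag_lowpass(h, hi, rate) else h
  }
  e <- rowSums(sapply(1:3, function(j) bp(frame$accel[, j]))^2)
  w <- max(3L, as.integer(round(window * rate)))
  if (w > length(e)) stop("window longer than the record")
  ma <- stats::filter(e, rep(1 / w, w), sides = 2)
  ma <- as.numeric(ma)
  # extend edge values so the series has full length
  first <- which(!is.na(ma))[1]
  last <- max(which(!is.na(ma)))
  ma[seq_len(first - 1)] <- ma[first]
  if (last < length(ma)) ma[(last + 1):length(ma)] <- ma[last]
  sqrt(ma)
}

#' Calibrate accelerometer vibration against a reference speed
#'
#' Fits `log(RMS) = intercept + slope * log(speed)` by least squares over
#' samples where the reference speed is valid, giving a deployment-specific
#' model that maps the high-frequency vibration ("jiggle") level of the
#' accelerometers to swim speed. Requires at least 30 valid samples
#' spanning at least 2 m/s of speed.
#'
#' @param frame A full-rate [sensor_frame()].
#' @param ref_speed Reference speed series aligned with `frame` (m/s,
#'   `NA` where invalid), e.g. from [speed_from_depth_rate()].
#' @param band Vibration band in Hz.
#' @param window RMS window in s.
#' @return A `jiggle_model` list: `intercept`, `slope`, `speed_range`,
#'   `rms_range`, `band`, `window`, `r_squared`, `n`.
#' @export
calibrate_jiggle_speed <- function(frame, ref_speed, band = c(10, 45),
                                   window = 1) {
  rms <- jiggle_rms(frame, band, window)
  ok <- is.finite(ref_speed) & ref_speed > 0.2 & is.finite(rms) & rms > 0
  if (sum(ok) < 30)
    stop("need at least 30 valid reference-speed samples to calibrate")
  if (diff(range(ref_speed[ok])) < 2)
    stop("reference speeds must span at least 2 m/s to calibrate")
  fit <- stats::lm(log(rms[ok]) ~ log(ref_speed[ok]))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("vibration RMS does not increase with speed")
  structure(list(
    intercept = unname(stats::coef(fit)[1]), slope = slope,
    speed_range = range(ref_speed[ok]), rms_range = range(rms[ok]),
    band = band, window = window,
    r_squared = summary(fit)$r.squared, n = sum(ok)
  ), class = "jiggle_model")
}

#' Swim speed from calibrated accelerometer vibration
#'
#' Maps the sliding-window vibration RMS through a [calibrate_jiggle_speed()]
#' model. Estimates are clamped to the calibrated speed range and flagged:
#' above the range the accelerometers may clip and the method
#' underestimates speed; below it the vibration is indistinguishable from
#' the noise floor.
#'
#' @param frame A full-rate [sensor_frame()].
#' @param model A `jiggle_model`.
#' @param window RMS window in s (defaults to the model's).
#' @return List: `speed` (m/s) and logical `flagged` (outside the
#'   calibration range).
#' @export
speed_from_jiggle <- function(frame, model, window = model$window) {
  stopifnot(inherits(model, "jiggle_model"))
  rms <- jiggle_rms(frame, model$band, window)
  u <- exp((log(pmax(rms, 1e-12)) - model$intercept) / model$slope)
  flagged <- u < model$speed_range[1] | u > model$speed_range[2]
  list(speed = pmin(pmax(u, model$speed_range[1]), model$speed_range[2]),
       flagged = flagged)
}

#' Detect breach events in a processed deployment
#'
#' Finds surfacings (depth at or above the surface threshold) that were
#' preceded by a rapid ascent, and walks each one back to the start of the
#' breaching maneuver. The exit is the first surface sample with positive
#' body pitch. The start is the later of (a) the last upward zero-crossing
#' of body pitch before the exit — the moment the body pitched past
#' horizontal — and (b) the onset of intensified fluking (the 2 s fluke
#' pitch RMS rising through a multiple of the deployment's quiet level),
#' which covers breaches begun while already ascending. When neither
#' signature is found the ascent onset itself is used and the segment is
#' flagged low confidence.
#'
#' @param frame A [sensor_frame()].
#' @param orientation Matching [estimate_orientation()] output.
#' @param config A [kin_config()].
#' @return A data frame of breach segments: `start`, `exit` (sample
#'   indices), `start_time`, `exit_time` (s), `start_depth` (m), and
#'   logical `low_confidence`. Zero rows when nothing is found.
#' @export
detect_breaches <- function(frame, orientation, config = kin_config()) {
  rate <- frame$rate
  n <- length(frame$depth)
  empty <- data.frame(start = integer(), exit = integer(),
                      start_time = numeric(), exit_time = numeric(),
                      start_depth = numeric(), low_confidence = logical())
  if (n < 10 * rate) return(empty)
  surface <- frame$depth <= config$surface_depth
  v_up <- -depth_rate(frame, config) # m/s, positive up
  bp <- orientation$body_pitch
  frms <- fluke_activity_rms(orientation, rate, config)
  thr <- config$fluke_intensify_factor *
    stats::quantile(frms, config$fluke_rms_quantile, na.rm = TRUE)

  # surfacing bout onsets
  onset <- which(surface & !c(FALSE, surface[-n]))
  segs <- list()
  last_exit <- 0L
  for (i0 in onset) {
    # exit: first sample of the bout with positive body pitch
    bout_end <- i0
    while (bout_end < n && surface[bout_end + 1L]) bout_end <- bout_end + 1L
    cand <- i0:bout_end
    cand <- cand[bp[cand] > 0]
    if (!length(cand)) next
    exit <- cand[1]
    if (exit - last_exit < 5 * rate) next
    # preceding ascent must be fast
    aw <- max(1L, exit - as.integer(config$ascent_window * rate)):max(1L, exit - 1L)
    if (mean(v_up[aw]) < config$min_ascent_speed) next
    # ascent onset: walk back while depth keeps increasing into the past
    j <- exit
    floor_idx <- max(1L, exit - as.integer(config$search_back * rate), last_exit + 1L)
    while (j > floor_idx && frame$depth[j - 1L] >= frame$depth[j] - 0.05)
      j <- j - 1L
    a0 <- j
    # (a) last upward zero-crossing of body pitch
    z_lo <- max(1L, a0 - as.integer(2 * rate))
    zz <- z_lo:(exit - 1L)
    up <- zz[bp[zz] <= 0 & bp[zz + 1L] > 0]
    z0 <- if (length(up)) up[length(up)] + 1L else NA_integer_
    # (b) fluking intensification onset; the threshold also has to clear
    # half the burst's own RMS so that low-frequency leakage of the
    # pitch-up into the fluke band cannot trip it early
    f_lo <- max(2L, a0 - as.integer(10 * rate))
    ff <- f_lo:(exit - 1L)
    thr_loc <- max(thr, config$fluke_local_fraction *
                     stats::quantile(frms[a0:exit], 0.9, na.rm = TRUE))
    rise <- ff[frms[ff - 1L] < thr_loc & frms[ff] >= thr_loc]
    # a genuine onset stays elevated; transient leakage bumps do not
    sustained <- vapply(rise, function(r) {
      seg <- r:min(r + as.integer(3 * rate), exit)
      mean(frms[seg] >= thr_loc, na.rm = TRUE) >= 0.7
    }, logical(1))
    rise <- rise[sustained]
    f0 <- if (length(rise)) rise[1] else NA_integer_
    start <- suppressWarnings(max(z0, f0, na.rm = TRUE))
    low_conf <- FALSE
    if (!is.finite(start)) {
      start <- a0
      low_conf <- TRUE
    }
    if (start >= exit - as.integer(0.5 * rate)) {
      start <- min(a0, exit - as.integer(0.5 * rate))
      low_conf <- TRUE
    }
    segs[[length(segs) + 1L]] <- data.frame(
      start = start, exit = exit,
      start_time = frame$time[start], exit_time = frame$time[exit],
      start_depth = frame$depth[start], low_confidence = low_conf)
    last_exit <- exit
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

# fluke-activity level: trailing-window RMS of the fluke pitch after a
# second residual high-pass, which strips the sub-band leakage that a
# body-pitch step throws into the fluke signal
fluke_activity_rms <- function(orientation, rate, config) {
  f2 <- orientation$fluke_pitch -
    zero_lag_lowpass(orientation$fluke_pitch, config$pitch_split_hz, rate,
                     config$filter_order)
  sliding_rms(f2, config$fluke_rms_window * rate, sides = 1)
}

# sliding RMS with edge extension; sides = 1 gives a trailing window so
# onset crossings lag rather than anticipate a burst
sliding_rms <- function(x, w, sides = 2) {
  w <- max(3L, as.integer(round(w)))
  ma <- as.numeric(stats::filter(x^2, rep(1 / w, w), sides = sides))
  first <- which(!is.na(ma))[1]
  last <- max(which(!is.na(ma)))
  ma[seq_len(first - 1)] <- ma[first]
  if (last < length(ma)) ma[(last + 1):length(ma)] <- ma[last]
  sqrt(pmax(ma, 0))
}

#' Count fluke strokes in a breach segment
#'
#' One stroke is a full tail-beat cycle — successive same-direction
#' zero-crossings of the high-pass (fluke) pitch signal. With `m`
#' crossings inside the segment the count is `(m - 1) / 2` full cycles,
#' which drops the trailing half-stroke at the water exit and counts an
#' odd leading half-stroke as 0.5. A partial leading cycle before the
#' first crossing is added as a fraction of the median stroke period.
#'
#' @param fluke_pitch Fluke (high-pass) pitch series in degrees.
#' @param segment One row of [detect_breaches()] output (or a list with
#'   `start` and `exit` sample indices).
#' @param rate Sampling rate in Hz.
#' @return List: `n_strokes` (may be fractional) and `stroke_frequency`
#'   (Hz, `n_strokes` over the segment duration).
#' @export
count_strokes <- function(fluke_pitch, segment, rate) {
  i0 <- segment$start
  i1 <- segment$exit
  if (i1 - i0 < rate) stop("segment shorter than 1 s")
  x <- fluke_pitch[i0:i1]
  dur <- (i1 - i0) / rate
  # snap numerically-zero samples to zero so a cycle boundary that lands
  # on the grid still registers; then a crossing is a sign change between
  # consecutive nonzero samples, and a zero run at either boundary is a
  # crossing of its own
  z <- x
  z[abs(z) < 1e-9 * max(abs(z), 1e-12)] <- 0
  s <- sign(z)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(n_strokes = 0, stroke_frequency = 0))
  ch <- which(s[nz][-1] != s[nz][-length(nz)])
  cross <- nz[ch + 1]
  if (nz[1] > 1) cross <- c(1L, cross)                      # leading zeros
  if (nz[length(nz)] < length(s)) cross <- c(cross, nz[length(nz)] + 1L)
  m <- length(cross)
  if (m < 2) return(list(n_strokes = 0, stroke_frequency = 0))
  n <- (m - 1) / 2
  period <- 2 * stats::median(diff(cross)) / rate
  lead <- min((cross[1] - 1) / rate / period, 0.99)
  n <- n + lead
  list(n_strokes = n, stroke_frequency = n / dur)
}

#' Classify the underwater trajectory of a breach
#'
#' Rule-based labels for the four approach shapes, decided from the 16 s
#' of context before the segment start (thresholds in [kin_config()]):
#' \describe{
#'   \item{I}{station-holding: |depth rate| below 0.3 m/s at depth > 5 m
#'     for at least 5 s, then a direct ascent.}
#'   \item{J}{slow unpowered ascent: upward rate between 0.05 and
#'     0.5 m/s with the fluke RMS below the intensification threshold for
#'     at least 5 s before the burst.}
#'   \item{V}{a descent of at least 3 m that began at a surfacing within
#'     30 s of the start, immediately followed by the breach ascent.}
#'   \item{U}{shallow start (depth at most 5 m) with at least 2 s of
#'     near-horizontal travel (|body pitch| < 20 deg) before the final
#'     pitch-up.}
#' }
#' `"unclassified"` when no rule fires.
#'
#' @param frame A [sensor_frame()].
#' @param orientation Matching orientation series.
#' @param segment One row of [detect_breaches()] output.
#' @param config A [kin_config()].
#' @return One of `"U"`, `"V"`, `"I"`, `"J"`, `"unclassified"`.
#' @export
classify_trajectory <- function(frame, orientation, segment,
                                config = kin_config()) {
  rate <- frame$rate
  i0 <- segment$start
  pre <- max(1L, i0 - as.integer(config$context_window * rate)):max(1L, i0 - 1L)
  if (length(pre) < 2 * rate) return("unclassified")
  v_up <- -depth_rate(frame, config)
  depth <- frame$depth
  frms <- fluke_activity_rms(orientation, rate, config)
  thr <- config$fluke_intensify_factor *
    stats::quantile(frms, config$fluke_rms_quantile, na.rm = TRUE)
  # signature window: the quiet_s seconds before the start, stopping 1 s
  # short of it (the zero-phase filters smear the burst backwards)
  qw <- max(1L, i0 - as.integer((config$class_IJ_quiet_s + 1) * rate)):
    max(1L, i0 - as.integer(1 * rate))
  frac <- function(cond) mean(cond, na.rm = TRUE)
  if (frac(abs(v_up[qw]) < config$class_I_max_rate &
           depth[qw] > config$class_I_min_depth) >= 0.9)
    return("I")
  if (frac(v_up[qw] > config$class_J_min_rate &
           v_up[qw] < config$class_J_max_rate &
           frms[qw] < max(thr, config$fluke_quiet_level) &
           depth[qw] > config$class_I_min_depth) >= 0.9)
    return("J")
  # V: last surfacing within the lookback, with >= 3 m of descent to the start
  lb <- max(1L, i0 - as.integer(config$class_V_lookback * rate)):i0
  surf <- lb[depth[lb] <= config$surface_depth]
  if (length(surf)) {
    s_last <- surf[length(surf)]
    if (depth[i0] - depth[s_last] >= config$class_V_min_descent &&
        mean(v_up[s_last:i0] <= 0.05, na.rm = TRUE) >= 0.8)
      return("V")
  }
  if (depth[i0] <= config$class_U_max_depth &&
      sum(abs(orientation$body_pitch[pre]) < config$class_U_flat_pitch) >=
        config$class_U_flat_s * rate)
    return("U")
  "unclassified"
}

#' Assemble the metrics of one breach
#'
#' Computes the depth at the start of the breaching acceleration, its
#' duration, stroke count and frequency, the exit speed (from
#' orientation-corrected depth rate when the exit pitch exceeds 30 deg,
#' otherwise from the calibrated vibration model when one is supplied),
#' exit pitch and roll (roll reported `NA` at gimbal lock), the emergence
#' fraction from the ballistic cylinder model, the full/partial class,
#' and the trajectory shape.
#'
#' @param frame A [sensor_frame()].
#' @param orientation Matching orientation series.
#' @param segment One row of [detect_breaches()] output.
#' @param body_length Body length in m for the emergence model.
#' @param jiggle_model Optional `jiggle_model` for low-pitch exits.
#' @param config A [kin_config()].
#' @return A one-row data frame: `depth`, `duration`, `n_strokes`,
#'   `stroke_frequency`, `exit_speed`, `speed_method`, `exit_pitch`,
#'   `exit_roll`, `emergence`, `full_breach`, `trajectory_class`.
#' @export
breach_metrics <- function(frame, orientation, segment, body_length,
                           jiggle_model = NULL, config = kin_config()) {
  rate <- frame$rate
  i1 <- segment$exit
  n <- length(frame$depth)
  # exit pitch settles just after the tag clears the water; the median
  # over the following ~0.6 s avoids the zero-phase filters' undershoot
  # of a pitch ramp that ends exactly at the exit
  post <- i1:min(n, i1 + as.integer(0.6 * rate))
  exit_pitch <- stats::median(orientation$pitch[post])
  exit_roll <- if (orientation$roll_undefined[i1] ||
                   abs(exit_pitch) >= config$gimbal_pitch) NA_real_ else
    orientation$roll[i1]
  strokes <- tryCatch(count_strokes(orientation$fluke_pitch, segment, rate),
                      error = function(e)
                        list(n_strokes = NA_real_, stroke_frequency = NA_real_))

  if (abs(exit_pitch) > config$min_pitch_speed) {
    # orientation-corrected depth rate at the exit: fit the vertical rate
    # over the final ascending ~1.5 s (quadratic when the pitch is still
    # developing, as in a late pitch-up), evaluate it at the exit, and
    # divide by the sine of the settled exit pitch
    v_up <- -deriv_center(frame$depth, rate)
    win <- max(segment$start, i1 - as.integer(1.5 * rate)):(i1 - 2L)
    win <- win[v_up[win] > 0.3 * max(v_up[win])]
    tt <- frame$time[win] - frame$time[i1]
    dpitch <- abs(orientation$pitch[i1] -
                    orientation$pitch[max(1L, i1 - as.integer(2 * rate))])
    exit_speed <- if (length(win) >= 5) {
      fit <- if (dpitch > 15 && length(win) > 8)
        stats::lm(v_up[win] ~ tt + I(tt^2)) else stats::lm(v_up[win] ~ tt)
      unname(stats::predict(fit, newdata = data.frame(tt = 0))) /
        sin(exit_pitch * pi / 180)
    } else {
      stats::median(v_up[win]) / sin(exit_pitch * pi / 180)
    }
    method <- "depth_rate"
  } else if (!is.null(jiggle_model)) {
    sp <- speed_from_jiggle(frame, jiggle_model)
    jwin <- max(segment$start, i1 - as.integer(rate)):max(segment$start, i1 - 1L)
    exit_speed <- stats::median(sp$speed[jwin], na.rm = TRUE)
    method <- "jiggle"
  } else {
    warning("exit pitch below the depth-rate threshold and no jiggle model supplied")
    exit_speed <- NA_real_
    method <- "none"
  }
  emergence <- if (is.finite(exit_speed) && exit_pitch > 0) {
    emergence_fraction(exit_speed, min(exit_pitch, 90), body_length,
                       g = config$g, cap = config$emergence_cap)
  } else NA_real_
  data.frame(
    depth = segment$start_depth,
    duration = (i1 - segment$start) / rate,
    n_strokes = strokes$n_strokes,
    stroke_frequency = strokes$stroke_frequency,
    exit_speed = exit_speed,
    speed_method = method,
    exit_pitch = exit_pitch,
    exit_roll = exit_roll,
    emergence = emergence,
    full_breach = !is.na(emergence) &&
      emergence > config$full_breach_threshold,
    trajectory_class = classify_trajectory(frame, orientation, segment, config),
    stringsAsFactors = FALSE
  )
}
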