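#' Construct a sensor frame
#'
#' A `sensor_frame` holds a uniformly sampled biologger time series: depth
#' (m, positive down), three-axis acceleration (units of g, surge/sway/heave)
#' and three-axis magnetics (arbitrary units), with the sampling rate in Hz.
#' Time is seconds since deployment start on a uniform grid.
#'
#' @param time Numeric vector of sample times (s), strictly increasing with
#'   constant step `1/rate`.
#' @param depth Numeric vector of depths (m, positive down).
#' @param accel n-by-3 numeric matrix of acceleration in g (columns
#'   surge `ax`, sway `ay`, heave `az`).
#' @param mag n-by-3 numeric matrix of magnetic field (columns `mx`,`my`,`mz`).
#' @param rate Sampling rate in Hz. Inferred from the median time step when
#'   omitted.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `sensor_frame`.
#' @export
sensor_frame <- function(time, depth, accel, mag, rate = NULL, validate = TRUE) {
  accel <- as_matrix3(accel, "accel")
  mag <- as_matrix3(mag, "mag")
  time <- as.numeric(time)
  depth <- as.numeric(depth)
  if (is.null(rate)) {
    if (length(time) < 2L) stop("rate must be given for frames with < 2 samples")
    rate <- 1 / stats::median(diff(time))
  }
  x <- structure(
    list(time = time, depth = depth, accel = accel, mag = mag,
         rate = as.numeric(rate)),
    class = "sensor_frame"
  )
  if (validate) validate_sensor_frame(x)
  x
}

as_matrix3 <- function(m, what) {
  m <- as.matrix(m)
  if (length(m) == 0L) m <- matrix(numeric(0), ncol = 3L)
  if (ncol(m) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Validate a sensor frame
#'
#' Checks the container invariants: equal channel lengths, a uniform time
#' grid (step `1/rate` within 1e-6 s), finite channels, and depth above
#' -1 m (brief negative excursions from surface noise are tolerated).
#'
#' @param x A `sensor_frame`.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_sensor_frame <- function(x) {
  n <- length(x$time)
  if (length(x$depth) != n || nrow(x$accel) != n || nrow(x$mag) != n)
    stop("channel lengths differ")
  if (!is.finite(x$rate) || x$rate <= 0) stop("rate must be a positive number")
  if (n > 1L) {
    dt <- diff(x$time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (max(abs(dt - 1 / x$rate)) > 1e-6)
      stop("time grid is not uniform at 1/rate (tolerance 1e-6 s)")
  }
  if (n > 0L) {
    if (!all(is.finite(x$depth)) || !all(is.finite(x$accel)) ||
        !all(is.finite(x$mag)))
      stop("all channels must be finite")
    if (min(x$depth) < -1) stop("depth below -1 m: check sign convention")
  }
  invisible(x)
}

#' @export
print.sensor_frame <- function(x, ...) {
  n <- length(x$time)
  dur <- if (n > 0) x$time[n] - x$time[1] + 1 / x$rate else 0
  cat(sprintf("<sensor_frame> %d samples @ %g Hz (%.1f s), depth %0.1f-%0.1f m\n",
              n, x$rate, dur,
              if (n) min(x$depth) else NA, if (n) max(x$depth) else NA))
  invisible(x)
}

#' @export
length.sensor_frame <- function(x) length(x$time)

#' Read a tag time series from delimited text
#'
#' Expects a header with columns `time,depth,ax,ay,az,mx,my,mz` (any order,
#' extra columns ignored). The sampling rate is inferred from the median
#' time step and the grid is validated.
#'
#' @param path Path to a CSV file.
#' @return A [sensor_frame()].
#' @export
read_tag_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", "depth", "ax", "ay", "az", "mx", "my", "mz")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop(sprintf("tag file lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (nrow(d) == 0L)
    stop("tag file has no data rows; rate cannot be inferred")
  sensor_frame(
    time = d$time, depth = d$depth,
    accel = cbind(d$ax, d$ay, d$az),
    mag = cbind(d$mx, d$my, d$mz)
  )
}

#' Write a tag time series as delimited text
#'
#' Values are written with enough precision (15 significant digits) that
#' `read_tag_csv(write_tag_csv(x))` reproduces the frame.
#'
#' @param frame A [sensor_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_csv <- function(frame, path) {
  validate_sensor_frame(frame)
  d <- data.frame(
    time = frame$time, depth = frame$depth,
    ax = frame$accel[, 1], ay = frame$accel[, 2], az = frame$accel[, 3],
    mx = frame$mag[, 1], my = frame$mag[, 2], mz = frame$mag[, 3]
  )
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter specification
#'
#' @param kind `"low-pass"` or `"high-pass"`.
#' @param cutoff Cutoff frequency in Hz; must lie below the Nyquist
#'   frequency of the series it is applied to.
#' @param order Butterworth order (default 2; applied forward-backward, so
#'   effectively 4th order).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("low-pass", "high-pass"), cutoff, order = 2L) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (order < 1) stop("order must be a positive integer")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order)),
            class = "filter_spec")
}

# Forward-backward Butterworth low-pass with reflective edge padding.
# The pad is sized to cover the filter's settling length at the cutoff
# (at least 3 cutoff periods), which keeps edges usable for the slow
# (0.2 Hz) body-pitch split on short segments.
zero_lag_lowpass <- function(x, cutoff, rate, order = 2L) {
  n <- length(x)
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(3 * rate / cutoff)))
  if (pad > 0L) {
    # odd (point-reflected) extension keeps the signal value and slope
    head_ext <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_ext, x, tail_ext)
  } else {
    xp <- x
  }
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-lag Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward (zero phase shift),
#' with reflective padding at the edges. High-pass output is computed as
#' the residual `signal - low-pass(signal)` so that the low/high split at a
#' common cutoff is exactly additive.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
zero_lag_filter <- function(x, spec, rate) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= rate / 2)
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$cutoff, rate / 2))
  if (length(x) <= 3L * spec$order)
    stop("signal too short for the requested filter order")
  lp <- zero_lag_lowpass(x, spec$cutoff, rate, spec$order)
  if (spec$kind == "low-pass") lp else x - lp
}

#' Downsample a sensor frame by integer decimation
#'
#' Anti-alias low-pass filters every channel (zero-lag Butterworth at 40%
#' of the target rate) and keeps every `rate/target_rate`-th sample.
#'
#' @param frame A [sensor_frame()].
#' @param target_rate Target rate in Hz; must divide `frame$rate`.
#' @return A [sensor_frame()] at `target_rate`.
#' @export
downsample <- function(frame, target_rate) {
  validate_sensor_frame(frame)
  fac <- frame$rate / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop(sprintf("target rate %g Hz does not divide %g Hz", target_rate,
                 frame$rate))
  fac <- as.integer(round(fac))
  if (fac == 1L) return(frame)
  cutoff <- 0.4 * target_rate
  lp <- function(v) zero_lag_lowpass(v, cutoff, frame$rate)
  keep <- seq(1L, length(frame$time), by = fac)
  sensor_frame(
    time = frame$time[keep],
    depth = lp(frame$depth)[keep],
    accel = apply(frame$accel, 2, lp)[keep, , drop = FALSE],
    mag = apply(frame$mag, 2, lp)[keep, , drop = FALSE],
    rate = target_rate
  )
}
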