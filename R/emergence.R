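#' Ballistic cylinder model of breach emergence
#'
#' Models the whale as a uniform, neutrally buoyant cylinder of length
#' `body_length` leaving the water along a straight path at angle
#' `exit_pitch` with speed `exit_speed`. Once a fraction E of the body is
#' above the surface the net along-path deceleration is `g sin(theta) E`
#' (the emerged fraction is no longer supported by buoyancy), so the energy
#' balance `U^2/2 = g sin(theta) L E^2 / 2` at the apex gives
#'
#'   E = U / sqrt(g L sin(theta))
#'
#' Drag and fluking during the emergence are ignored. The fraction is
#' capped at 1.2: tagged whales have been observed clearing the water by up
#' to 120% of body length, and the momentum of the flukes can carry the
#' body slightly beyond the cylinder prediction.
#'
#' @param exit_speed Along-path speed at the surface (m/s), >= 0.
#' @param exit_pitch Exit pitch angle in degrees, in (0, 90].
#' @param body_length Body length in m, > 0.
#' @param g Gravitational acceleration (m/s^2).
#' @param cap Maximum reported fraction (default 1.2).
#' @return Fraction of body length emerged at the apex (0 to `cap`).
#' @export
emergence_fraction <- function(exit_speed, exit_pitch, body_length,
                               g = 9.81, cap = 1.2) {
  if (any(exit_pitch <= 0) || any(exit_pitch > 90))
    stop("exit_pitch must be in (0, 90] degrees")
  if (any(exit_speed < 0)) stop("exit_speed must be >= 0")
  if (any(body_length <= 0)) stop("body_length must be positive")
  e <- exit_speed / sqrt(g * body_length * sin(exit_pitch * pi / 180))
  pmin(e, cap)
}

#' Minimum exit speed for a target emergence
#'
#' Exact inverse of [emergence_fraction()] (below the cap):
#' `U = E sqrt(g L sin(theta))`.
#'
#' @param target_fraction Desired emergence fraction, in (0, 1.2].
#' @inheritParams emergence_fraction
#' @return Exit speed in m/s.
#' @export
min_exit_speed <- function(target_fraction, exit_pitch, body_length, g = 9.81) {
  if (any(exit_pitch <= 0) || any(exit_pitch > 90))
    stop("exit_pitch must be in (0, 90] degrees")
  if (any(target_fraction < 0) || any(target_fraction > 1.2))
    stop("target_fraction must be in [0, 1.2]")
  target_fraction * sqrt(g * body_length * sin(exit_pitch * pi / 180))
}

#' Classify a breach as full or partial
#'
#' A breach is "full" when strictly more than 40% of the body emerges.
#'
#' @param fraction Emergence fraction(s), >= 0.
#' @param threshold Full-breach cutoff (default 0.40).
#' @return Character vector, `"full"` or `"partial"`.
#' @export
classify_breach <- function(fraction, threshold = 0.40) {
  if (any(fraction < 0)) stop("fraction must be >= 0")
  ifelse(fraction > threshold, "full", "partial")
}
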