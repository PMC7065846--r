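#' Morphometry of a tagged whale
#'
#' @param species Species label (free text).
#' @param L_body Body length in m.
#' @param w_max Maximum body width in m (defaults to 18% of body length,
#'   the average width-to-length ratio of the photogrammetry whales).
#' @param M_body Body mass in kg.
#' @param muscle_fraction Locomotor muscle mass as a fraction of body mass
#'   (default 0.132).
#' @return A `morphometry` list.
#' @export
morphometry <- function(species = "humpback", L_body, w_max = 0.18 * L_body,
                        M_body, muscle_fraction = 0.132) {
  if (L_body <= 0 || M_body <= 0) stop("length and mass must be positive")
  if (w_max <= 0 || w_max >= L_body) stop("w_max must be in (0, L_body)")
  if (muscle_fraction <= 0 || muscle_fraction >= 1)
    stop("muscle_fraction must be in (0, 1)")
  structure(list(species = species, L_body = L_body, w_max = w_max,
                 M_body = M_body, muscle_fraction = muscle_fraction),
            class = "morphometry")
}

#' Speed profile of an acceleration event
#'
#' The event is split into a linear acceleration phase (speed ramps from
#' `U_i` to `U_f` over `T_acc` seconds) and an optional plateau at `U_f`
#' for `T_plat` seconds.
#'
#' @param U_i Initial speed (m/s), >= 0.
#' @param U_f Final speed (m/s), > `U_i`.
#' @param T_acc Acceleration duration (s), > 0.
#' @param T_plat Plateau duration (s), >= 0 (default 0).
#' @return A `speed_profile` list.
#' @export
speed_profile <- function(U_i, U_f, T_acc, T_plat = 0) {
  if (U_i < 0 || U_f < U_i) stop("need U_f >= U_i >= 0")
  if (T_acc <= 0 || T_plat < 0) stop("need T_acc > 0 and T_plat >= 0")
  structure(list(U_i = U_i, U_f = U_f, T_acc = T_acc, T_plat = T_plat),
            class = "speed_profile")
}

#' Hydrodynamic and metabolic coefficients
#'
#' Defaults are the values used throughout the energetics model: seawater
#' density 1027 kg/m^3; kinematic viscosity 1.0e-6 m^2/s (seawater spans
#' about 1.0-1.4e-6 over the relevant temperatures, and drag depends on
#' viscosity only through its 0.2 power); drag amplification F = 2 for the
#' extra drag of the heaving body and tail during active swimming;
#' added-mass coefficient k = 0.045 for a whale-shaped body; wave-drag
#' factor gamma = 1 (no wave drag: breaching ascents are steep, so the
#' body is not translating along the surface); metabolic efficiency 0.25
#' and propulsive efficiency 0.75.
#'
#' @param rho_w Seawater density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @param F_amp Active-swimming drag amplification factor.
#' @param k Added-mass coefficient.
#' @param gamma Wave-drag amplification (1 = none).
#' @param eta_metab Metabolic efficiency.
#' @param eta_prop Propulsive efficiency.
#' @param g Gravitational acceleration (m/s^2).
#' @return A `hydro_coefficients` list.
#' @export
hydro_coefficients <- function(rho_w = 1027, nu = 1.0e-6, F_amp = 2,
                               k = 0.045, gamma = 1, eta_metab = 0.25,
                               eta_prop = 0.75, g = 9.81) {
  vals <- c(rho_w, nu, k, gamma, g)
  if (any(vals <= 0) || F_amp < 0) stop("coefficients must be positive")
  if (eta_metab <= 0 || eta_metab > 1 || eta_prop <= 0 || eta_prop > 1)
    stop("efficiencies must lie in (0, 1]")
  structure(list(rho_w = rho_w, nu = nu, F_amp = F_amp, k = k, gamma = gamma,
                 eta_metab = eta_metab, eta_prop = eta_prop, g = g),
            class = "hydro_coefficients")
}

#' Wetted surface area from body mass
#'
#' Allometric relation `S_wet = 0.08 M^0.65` (m^2, M in kg).
#'
#' @param M_body Body mass in kg, > 0.
#' @return Wetted surface area in m^2.
#' @export
wetted_area <- function(M_body) {
  if (any(M_body <= 0)) stop("mass must be positive")
  0.08 * M_body^0.65
}

#' Default species mass-length registry
#'
#' Power laws `M = a L^b` (kg, m) per species. The shipped humpback entry
#' is fitted (log-log least squares) to the five reference
#' length/mass pairs used by the energetics reconstructions, because the
#' original whaling-data regression coefficients are not part of this
#' package's inputs; override with published coefficients via `extra`.
#'
#' @param extra Named list of `c(a, b)` entries to add or override.
#' @return Named list of coefficient pairs.
#' @export
mass_length_registry <- function(extra = NULL) {
  ref_L <- c(7.8, 10.5, 12.7, 14.7, 14.8)
  ref_M <- c(7000, 17000, 30000, 46000, 46000)
  fit <- stats::lm(log(ref_M) ~ log(ref_L))
  reg <- list(humpback = c(a = unname(exp(stats::coef(fit)[1])),
                           b = unname(stats::coef(fit)[2])))
  if (!is.null(extra)) reg[names(extra)] <- extra
  reg
}

#' Estimate body mass from body length
#'
#' Evaluates the species power law `a L^b` and rounds to the nearest
#' 1000 kg, the precision at which whale masses are meaningfully known.
#'
#' @param species Species name present in `registry`.
#' @param L_body Body length in m.
#' @param registry A registry from [mass_length_registry()].
#' @return Body mass in kg, rounded to the nearest 1000.
#' @export
mass_from_length <- function(species, L_body, registry = mass_length_registry()) {
  if (!species %in% names(registry))
    stop(sprintf("unknown species '%s'; available: %s", species,
                 paste(names(registry), collapse = ", ")))
  ab <- registry[[species]]
  round(ab[["a"]] * L_body^ab[["b"]] / 1000) * 1000
}

#' Reynolds number
#'
#' @param L_body Body length in m.
#' @param U Speed in m/s (0 allowed; returns 0).
#' @param nu Kinematic viscosity in m^2/s.
#' @return Dimensionless Reynolds number `L U / nu`.
#' @export
reynolds <- function(L_body, U, nu = 1.0e-6) {
  if (any(L_body <= 0) || any(nu <= 0)) stop("L_body and nu must be positive")
  if (any(U < 0)) stop("U must be >= 0")
  L_body * U / nu
}

# shape (pressure-gradient) factor of the airship drag formula
drag_shape_factor <- function(width_ratio) {
  1 + 1.5 * width_ratio^1.5 + 7.0 * width_ratio^3
}

#' Drag coefficient of an actively swimming whale
#'
#' Airship-derived formula: a turbulent-friction term `0.072 Re^-0.2`
#' times a pressure-gradient shape factor
#' `1 + 1.5 r^1.5 + 7 r^3` (r = width/length), amplified by `F_amp` for
#' the heaving body and optionally by `gamma` for near-surface wave drag.
#' Valid for high Reynolds number flow (Re > 1e6); a warning is issued
#' below that.
#'
#' @param Re Reynolds number, > 0.
#' @param width_ratio `w_max / L_body`.
#' @param F_amp Drag amplification factor.
#' @param gamma Wave-drag factor (default 1).
#' @return Dimensionless drag coefficient referenced to wetted area.
#' @export
drag_coefficient <- function(Re, width_ratio, F_amp = 2, gamma = 1) {
  if (any(Re <= 0)) stop("Re must be positive")
  if (any(Re <= 1e6))
    warning("Re <= 1e6: outside the high-Reynolds regime the friction law assumes")
  gamma * F_amp * (0.072 / Re^0.2) * drag_shape_factor(width_ratio)
}

# common prefactor F_amp * gamma * 1/2 rho S_wet * (0.072/Re_f^0.2) * shape
drag_work_prefactor <- function(morph, Uf, coeffs) {
  Re <- reynolds(morph$L_body, Uf, coeffs$nu)
  coeffs$gamma * coeffs$F_amp * 0.5 * coeffs$rho_w * wetted_area(morph$M_body) *
    (0.072 / Re^0.2) * drag_shape_factor(morph$w_max / morph$L_body)
}

#' Drag work at constant speed (plateau phase)
#'
#' `W = F 1/2 rho S_wet Cd(U_f) U_f^3 T_plat`.
#'
#' @param morph A [morphometry()].
#' @param Uf Plateau speed (m/s).
#' @param T_plat Plateau duration (s).
#' @param coeffs A [hydro_coefficients()].
#' @return Work in J.
#' @export
work_drag_plateau <- function(morph, Uf, T_plat, coeffs = hydro_coefficients()) {
  if (T_plat < 0) stop("T_plat must be >= 0")
  if (T_plat == 0 || Uf == 0) return(0)
  drag_work_prefactor(morph, Uf, coeffs) * Uf^3 * T_plat
}

#' Drag work during a linear acceleration
#'
#' Closed-form time integral of the friction drag power over a linear
#' speed ramp `U(t) = U_i + (U_f - U_i) t / T_acc`, expressed with the
#' friction coefficient frozen at its final-speed Reynolds number:
#'
#'   W_fric = F 1/2 rho S_wet (0.072/Re_f^0.2) shape *
#'            (U_f^3.8 - U_i^3.8) / (3.8 (U_f - U_i)) * U_f^0.2 * T_acc
#'
#' plus the acceleration-reaction (added-mass) work
#' `1/2 k M (U_f^2 - U_i^2)`. In the limit `U_i -> U_f` the friction term
#' reduces continuously to the plateau formula over `T_acc`.
#'
#' @param morph A [morphometry()].
#' @param profile A [speed_profile()] (or list with `U_i`,`U_f`,`T_acc`).
#' @param coeffs A [hydro_coefficients()].
#' @return List with `friction`, `added_mass`, and `total` (J).
#' @export
work_drag_acceleration <- function(morph, profile,
                                   coeffs = hydro_coefficients()) {
  Ui <- profile$U_i; Uf <- profile$U_f; Tacc <- profile$T_acc
  pre <- drag_work_prefactor(morph, Uf, coeffs)
  # (U_f^3.8 - U_i^3.8)/(3.8 (U_f - U_i)) * U_f^0.2 -> U_f^3 as U_i -> U_f
  vel_int <- if (abs(Uf - Ui) < 1e-9 * max(Uf, 1)) {
    Uf^3
  } else {
    (Uf^3.8 - Ui^3.8) / (3.8 * (Uf - Ui)) * Uf^0.2
  }
  fric <- pre * vel_int * Tacc
  added <- 0.5 * coeffs$k * morph$M_body * (Uf^2 - Ui^2)
  list(friction = fric, added_mass = added, total = fric + added)
}

#' Energy budget of a breaching (or lunging) acceleration
#'
#' Assembles the mechanical work of the event — change in kinetic energy
#' of the body, added-mass work, friction drag work during the
#' acceleration, and drag work during any plateau — and converts it to
#' metabolic energy by dividing by `eta_metab * eta_prop`. Power metrics:
#' average muscle (mechanical) power is
#' `W_metab eta_metab / (T_acc + T_plat)`, and the peak is evaluated over
#' the final second of the linear acceleration via
#' [max_power_last_second()].
#'
#' @param morph A [morphometry()].
#' @param profile A [speed_profile()].
#' @param coeffs A [hydro_coefficients()].
#' @return An `energy_budget` list: work components (J), total mechanical
#'   and metabolic work (J), average and last-second muscle power (W), and
#'   mass- and muscle-mass-specific values.
#' @export
breach_energetics <- function(morph, profile, coeffs = hydro_coefficients()) {
  dKE_body <- 0.5 * morph$M_body * (profile$U_f^2 - profile$U_i^2)
  acc <- work_drag_acceleration(morph, profile, coeffs)
  plat <- work_drag_plateau(morph, profile$U_f, profile$T_plat, coeffs)
  thrust <- dKE_body + acc$added_mass + acc$friction + plat
  metab <- thrust / (coeffs$eta_metab * coeffs$eta_prop)
  T_tot <- profile$T_acc + profile$T_plat
  avg_musc <- metab * coeffs$eta_metab / T_tot
  max_musc <- max_power_last_second(morph, profile, coeffs)
  structure(list(
    dKE_body = dKE_body,
    dKE_added = acc$added_mass,
    W_drag_acc = acc$friction,
    W_drag_plat = plat,
    W_thrust_total = thrust,
    W_metab_total = metab,
    avg_muscle_power = avg_musc,
    max_muscle_power_last_s = max_musc,
    mass_specific_energy = metab / morph$M_body,
    mass_specific_power = max_musc / morph$M_body,
    muscle_specific_power = max_musc / (morph$muscle_fraction * morph$M_body)
  ), class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> W_metab %.3g MJ (thrust %.3g MJ = KE %.3g + added %.3g + drag %.3g/%.3g)\n",
              x$W_metab_total / 1e6, x$W_thrust_total / 1e6, x$dKE_body / 1e6,
              x$dKE_added / 1e6, x$W_drag_acc / 1e6, x$W_drag_plat / 1e6))
  cat(sprintf("  muscle power: avg %.3g kW, last-second %.3g kW; %.3g J/kg, %.3g W/kg body, %.3g W/kg muscle\n",
              x$avg_muscle_power / 1e3, x$max_muscle_power_last_s / 1e3,
              x$mass_specific_energy, x$mass_specific_power,
              x$muscle_specific_power))
  invisible(x)
}

#' Muscle power over the final second of the acceleration
#'
#' Evaluates the metabolic work accrued over the sub-interval
#' `[T_acc - 1, T_acc]` of the linear ramp (initial speed `U(T_acc - 1)`)
#' and multiplies by `eta_metab` to express it as muscle mechanical power.
#' For `T_acc < 1` s the full acceleration window is used, with a warning.
#'
#' @inheritParams breach_energetics
#' @return Muscle mechanical power in W.
#' @export
max_power_last_second <- function(morph, profile,
                                  coeffs = hydro_coefficients()) {
  window <- 1
  if (profile$T_acc < 1) {
    warning("T_acc < 1 s: last-second power evaluated over the full acceleration")
    window <- profile$T_acc
  }
  a_avg <- (profile$U_f - profile$U_i) / profile$T_acc
  U_start <- profile$U_f - a_avg * window
  sub <- speed_profile(U_i = U_start, U_f = profile$U_f, T_acc = window)
  dKE <- 0.5 * morph$M_body * (sub$U_f^2 - sub$U_i^2)
  acc <- work_drag_acceleration(morph, sub, coeffs)
  metab <- (dKE + acc$total) / (coeffs$eta_metab * coeffs$eta_prop)
  metab * coeffs$eta_metab / window
}
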