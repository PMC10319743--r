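#' Reflection phase of a reactive impedance surface
#'
#' A surface of impedance Z_s = R + jX illuminated at normal incidence from a
#' medium of intrinsic impedance eta reflects with coefficient
#' Gamma = (Z_s - eta) / (Z_s + eta); the reflection phase is
#' phi = Im[Ln(Gamma)] on the principal branch, reported in degrees in
#' (-180, 180]. A short (Z_s = 0) behaves as a perfect electric conductor
#' (phi = 180 deg); an open (X -> Inf) as an artificial magnetic conductor
#' (phi -> 0). A purely reactive surface gives |Gamma| = 1. An inductive
#' surface (X > 0, R = 0) sweeps phi from 180 deg down to 0 as X grows.
#'
#' @param reactance Surface reactance X in ohms (signed; > 0 inductive,
#'   < 0 capacitive). Vectorised.
#' @param resistance Surface resistance in ohms (default 0, lossless).
#' @param eta Intrinsic impedance of the incident medium (ohms), default free
#'   space.
#' @return Reflection phase in degrees, in (-180, 180].
#' @examples
#' reflection_phase(0)       # 180: PEC
#' reflection_phase(1e9)     # ~0: AMC limit
#' reflection_phase(118.78)  # ~145: inductive surface
#' @export
reflection_phase <- function(reactance, resistance = 0, eta = .eta0) {
  if (eta <= 0) abort("`eta` must be > 0.")
  zs <- complex(real = resistance, imaginary = reactance)
  if (any(abs(zs + eta) == 0))
    abort("Z_s = -eta is singular: the reflection coefficient is unbounded.")
  gam <- (zs - eta) / (zs + eta)
  phi <- Arg(gam) * 180 / pi
  # principal branch gives (-180, 180]; map -180 (real negative axis) to +180
  ifelse(phi <= -180, phi + 360, phi)
}

#' Reactance required for a target reflection phase
#'
#' Closed-form inverse of [reflection_phase()] for a lossless inductive sheet:
#' X = eta * tan((180 - phi) / 2). Only phases strictly between 0 and 180
#' degrees are reachable with finite positive reactance; phi = 180 maps to
#' X = 0 (PEC).
#'
#' @param phase_target_deg Target phase in degrees, in (0, 180].
#' @param eta Intrinsic impedance of the incident medium (ohms).
#' @return Required reactance X in ohms.
#' @examples
#' required_reactance(145)  # ~118.8 ohm
#' required_reactance(90)   # equals eta
#' @export
required_reactance <- function(phase_target_deg, eta = .eta0) {
  if (any(phase_target_deg <= 0) || any(phase_target_deg > 180))
    abort("`phase_target_deg` must lie in (0, 180].")
  eta * tan((180 - phase_target_deg) / 2 * pi / 180)
}

#' Classify a surface from its reflection phase
#'
#' @param phase_deg Reflection phase in degrees, in (-180, 180].
#' @return One of `"PEC-like"` (180), `"AMC-like"` (0), `"inductive-RIS"`
#'   (0 < phi < 180), `"capacitive"` (phi < 0). Vectorised.
#' @examples
#' classify_surface(c(180, 145, 0, -30))
#' @export
classify_surface <- function(phase_deg) {
  if (any(phase_deg <= -180) || any(phase_deg > 180))
    abort("`phase_deg` must lie in (-180, 180].")
  dplyr::case_when(
    phase_deg == 180 ~ "PEC-like",
    phase_deg == 0 ~ "AMC-like",
    phase_deg > 0 ~ "inductive-RIS",
    TRUE ~ "capacitive"
  )
}
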