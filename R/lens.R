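#' Effective permittivity of a via-loaded dielectric lens
#'
#' Discrete-dipole (Maxwell Garnett) mixing rule for sub-wavelength dielectric
#' inclusions of permittivity `eps_via` occupying volume fraction `F` of a host
#' of permittivity `eps_host`:
#' \deqn{\varepsilon_{eff} = \varepsilon_H + \frac{3F\,\varepsilon_H\, r}
#'   {1 - F\, r}, \qquad r = \frac{\varepsilon_r - \varepsilon_H}
#'   {\varepsilon_r + 2\varepsilon_H}.}
#' The result always lies between host and inclusion permittivity.
#'
#' @param eps_via Inclusion (via-fill) relative permittivity, >= 1.
#' @param eps_host Host relative permittivity, >= 1.
#' @param volume_fraction Volume fraction F in `[0, 1)`.
#' @return Effective relative permittivity (vectorised).
#' @examples
#' dda_effective_permittivity(5.28, 3, 0.14)  # ~3.26
#' @export
dda_effective_permittivity <- function(eps_via, eps_host, volume_fraction) {
  if (any(eps_via < 1) || any(eps_host < 1))
    abort("Permittivities must be >= 1.")
  if (any(volume_fraction < 0) || any(volume_fraction >= 1))
    abort("`volume_fraction` must lie in [0, 1).")
  r <- (eps_via - eps_host) / (eps_via + 2 * eps_host)
  eps_host + 3 * volume_fraction * eps_host * r / (1 - volume_fraction * r)
}

#' Ideal matching-layer permittivity between two media
#'
#' A quarter-wave matching layer between media of permittivities eps_a and
#' eps_b is reflectionless when its permittivity is the geometric mean
#' sqrt(eps_a * eps_b).
#'
#' @param eps_a,eps_b Relative permittivities, >= 1.
#' @return sqrt(eps_a * eps_b), vectorised.
#' @examples
#' ideal_matching_permittivity(1, 38)  # air -> skin, ~6.16
#' @export
ideal_matching_permittivity <- function(eps_a, eps_b) {
  if (any(eps_a < 1) || any(eps_b < 1)) abort("Permittivities must be >= 1.")
  sqrt(eps_a * eps_b)
}

#' Quarter-wave matching thickness
#'
#' @param eps_match Matching-layer relative permittivity, >= 1.
#' @param freq Design frequency in Hz, > 0.
#' @return Thickness c / (4 f sqrt(eps_match)) in mm.
#' @examples
#' quarter_wave_thickness(3.3, 2.45e9)  # ~16.8 mm
#' @export
quarter_wave_thickness <- function(eps_match, freq) {
  if (any(eps_match < 1)) abort("`eps_match` must be >= 1.")
  if (any(freq <= 0)) abort("`freq` must be > 0.")
  1000 * .c0 / (4 * freq * sqrt(eps_match))
}

#' Electric-dipole validity of a via inclusion
#'
#' A cylindrical via of diameter D behaves as an electric dipole (so the mixing
#' rule of [dda_effective_permittivity()] applies) when its circumference is
#' sub-wavelength: pi D / lambda < 1. `lambda` is evaluated in the stated
#' medium (free space by default).
#'
#' @param diameter_mm Via diameter in mm, > 0.
#' @param freq Frequency in Hz.
#' @param eps_medium Relative permittivity of the medium defining lambda.
#' @return A tibble with `ratio` (pi D / lambda) and logical `valid`
#'   (`ratio < 1`).
#' @examples
#' dipole_approximation_valid(4, 2.45e9)  # ratio ~0.10, valid
#' @export
dipole_approximation_valid <- function(diameter_mm, freq, eps_medium = 1) {
  if (any(diameter_mm <= 0)) abort("`diameter_mm` must be > 0.")
  if (any(freq <= 0)) abort("`freq` must be > 0.")
  lambda_mm <- 1000 * .c0 / (freq * sqrt(eps_medium))
  ratio <- pi * diameter_mm / lambda_mm
  tibble(ratio = ratio, valid = ratio < 1)
}

#' Via volume fraction from geometry
#'
#' Helper computing F = n_vias * pi (D/2)^2 L_via / V_eff. The effective volume
#' `effective_volume_mm3` — the portion of the lens involved in propagation —
#' is an explicit user input: it depends on the aperture illumination, not on
#' the via geometry alone.
#'
#' @param n_vias Number of vias.
#' @param diameter_mm Via diameter (mm).
#' @param length_mm Via length (mm).
#' @param effective_volume_mm3 Effective host volume (mm^3), > total via volume.
#' @return Volume fraction F in `[0, 1)`.
#' @export
via_volume_fraction <- function(n_vias, diameter_mm, length_mm,
                                effective_volume_mm3) {
  v_vias <- n_vias * pi * (diameter_mm / 2)^2 * length_mm
  if (any(effective_volume_mm3 <= v_vias))
    abort("`effective_volume_mm3` must exceed the total via volume.")
  v_vias / effective_volume_mm3
}

#' Summarise a matching-lens design
#'
#' Convenience wrapper bundling the lens calculators for a design point: the
#' effective permittivity of the via-loaded host, the ideal (geometric-mean)
#' matching permittivity for a stated pair of media, the quarter-wave
#' thickness at the effective permittivity, and the dipole-criterion ratio.
#'
#' @param eps_host Host (lens material) relative permittivity.
#' @param eps_via Via-fill relative permittivity.
#' @param volume_fraction Via volume fraction F.
#' @param freq Design frequency (Hz).
#' @param via_diameter_mm Via diameter (mm).
#' @param eps_pair Length-2 vector of the media to be matched (default air and
#'   skin).
#' @return One-row tibble with `eps_eff`, `eps_ideal`, `quarter_wave_mm`,
#'   `dipole_ratio`, `dipole_valid`.
#' @examples
#' lens_design(eps_host = 3, eps_via = 5.28, volume_fraction = 0.14)
#' @export
lens_design <- function(eps_host = 3, eps_via = 5.28, volume_fraction = 0.14,
                        freq = 2.45e9, via_diameter_mm = 4,
                        eps_pair = c(1, 38)) {
  stopifnot(length(eps_pair) == 2L)
  eps_eff <- dda_effective_permittivity(eps_via, eps_host, volume_fraction)
  dip <- dipole_approximation_valid(via_diameter_mm, freq)
  tibble(
    eps_host = eps_host, eps_via = eps_via, volume_fraction = volume_fraction,
    eps_eff = eps_eff,
    eps_ideal = ideal_matching_permittivity(eps_pair[1], eps_pair[2]),
    quarter_wave_mm = quarter_wave_thickness(eps_eff, freq),
    dipole_ratio = dip$ratio, dipole_valid = dip$valid
  )
}
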