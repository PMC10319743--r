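#' Complex relative permittivity of a lossy tissue
#'
#' Returns eps' - j sigma/(omega eps0) (relative), the complex permittivity
#' under the e^{+j omega t} phasor convention used by the scalar plane-wave
#' formulas in this module. The cylindrical mode-matching solver uses the
#' opposite time convention; see [cyl_layer()].
#'
#' @param tissue A one-row tissue tibble (see [tissue_properties()]) or a
#'   tissue name looked up in `registry`.
#' @param freq Frequency in Hz, > 0.
#' @param registry Registry used when `tissue` is a name.
#' @return Complex scalar (or vector if `tissue` has several rows).
#' @examples
#' complex_permittivity("skin", 2.45e9)  # 38 - 10.73i
#' @export
complex_permittivity <- function(tissue, freq, registry = tissue_registry()) {
  tissue <- resolve_tissue(tissue, registry)
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0)
    abort("`freq` must be a single positive frequency in Hz.")
  w <- 2 * pi * freq
  complex(real = tissue$eps_real, imaginary = -tissue$sigma / (w * .eps0))
}

#' Complex propagation constant in a lossy tissue
#'
#' Computes the attenuation coefficient alpha (Np/m) and phase constant beta
#' (rad/m) of a uniform plane wave in a conductive dielectric from the two
#' radical expressions
#' \deqn{\alpha = \omega \sqrt{\tfrac{\mu\varepsilon}{2}\left[\sqrt{1 +
#'   (\sigma/\omega\varepsilon)^2} - 1\right]}, \quad
#'   \beta = \omega \sqrt{\tfrac{\mu\varepsilon}{2}\left[\sqrt{1 +
#'   (\sigma/\omega\varepsilon)^2} + 1\right]}}
#' with mu = mu0 and epsilon = eps0 * eps_real.
#'
#' @inheritParams complex_permittivity
#' @return A one-row tibble with columns `tissue`, `freq`, `alpha` (Np/m),
#'   `beta` (rad/m) and `gamma` (complex, alpha + j beta). Multi-row tissue
#'   input gives one row per tissue.
#' @examples
#' propagation_constants("skin", 2.45e9)$alpha  # ~44.2 Np/m
#' @export
propagation_constants <- function(tissue, freq, registry = tissue_registry()) {
  tissue <- resolve_tissue(tissue, registry)
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0)
    abort("`freq` must be a single positive frequency in Hz.")
  w <- 2 * pi * freq
  eps <- .eps0 * tissue$eps_real
  q <- tissue$sigma / (w * eps)
  alpha <- w * sqrt(.mu0 * eps / 2 * (sqrt(1 + q^2) - 1))
  beta <- w * sqrt(.mu0 * eps / 2 * (sqrt(1 + q^2) + 1))
  tibble(
    tissue = tissue$tissue, freq = freq,
    alpha = alpha, beta = beta,
    gamma = complex(real = alpha, imaginary = beta)
  )
}

#' One-way power attenuation of a traversed layer, in dB
#'
#' Amplitude decays as exp(-alpha L) along a path of length L, so the power
#' attenuation is `10 * log10(exp(-alpha * L))` dB (always <= 0). The
#' two-pass doubling of a transceiver geometry is the caller's concern: build
#' paths with [layer_path()] or [diametric_path()], which double thicknesses.
#'
#' @inheritParams complex_permittivity
#' @param path_length_mm Traversed length in mm, > 0 (0 allowed, giving 0 dB).
#' @return Attenuation in dB (negative scalar, or vector over tissues).
#' @examples
#' layer_attenuation_db("skin", 4, 2.45e9)  # -0.77 dB
#' @export
layer_attenuation_db <- function(tissue, path_length_mm, freq,
                                 registry = tissue_registry()) {
  if (any(!is.finite(path_length_mm)) || any(path_length_mm < 0))
    abort("`path_length_mm` must be finite and >= 0.")
  pc <- propagation_constants(tissue, freq, registry)
  10 * log10(exp(-pc$alpha * path_length_mm / 1000))
}

#' Ordered tissue path for a transmit-receive traversal
#'
#' Builds a layered path as a tibble of (tissue, traversed length) segments.
#' With `double_pass = TRUE` (the default) each layer's one-way thickness is
#' doubled, reflecting a receiver on the opposite side of the limb so the wave
#' crosses every annular layer twice.
#'
#' @param tissues A tissue tibble (rows in traversal order) or character vector
#'   of names resolved in `registry`.
#' @param lengths_mm Optional traversed lengths; defaults to the registry
#'   thicknesses (doubled when `double_pass`).
#' @param double_pass Double the one-way thicknesses?
#' @param registry Registry used for name lookup.
#' @return A tibble of class `layer_path` with columns `tissue`, `length_mm`,
#'   and the tissue's dielectric columns; attribute `double_pass` records the
#'   convention.
#' @examples
#' layer_path(c("skin", "fat", "muscle", "bone"))
#' @export
layer_path <- function(tissues, lengths_mm = NULL, double_pass = TRUE,
                       registry = tissue_registry()) {
  tissues <- resolve_tissue(tissues, registry)
  if (is.null(lengths_mm)) {
    lengths_mm <- tissues$thickness_mm * if (double_pass) 2 else 1
  }
  if (length(lengths_mm) != nrow(tissues))
    abort("`lengths_mm` must have one entry per tissue segment.")
  if (any(!is.finite(lengths_mm)) || any(lengths_mm <= 0))
    abort("Segment lengths must be finite and > 0.")
  out <- tissues %>% mutate(length_mm = lengths_mm)
  attr(out, "double_pass") <- double_pass
  class(out) <- c("layer_path", class(out))
  out
}

#' Total attenuation along a layered path
#'
#' @param path A [layer_path()] (or [diametric_path()]) tibble.
#' @param freq Frequency in Hz.
#' @return A tibble with per-segment `attenuation_db` and, as attribute
#'   `total_db`, their sum.
#' @export
path_attenuation_db <- function(path, freq) {
  stopifnot(inherits(path, "layer_path"))
  att <- map_dbl(seq_len(nrow(path)), function(i)
    layer_attenuation_db(path[i, , drop = FALSE], path$length_mm[i], freq))
  out <- path %>% mutate(attenuation_db = att)
  attr(out, "total_db") <- sum(att)
  out
}

#' Cascaded power budget through stacked lossy layers
#'
#' Given ordered fractional power losses f_i of each stage, the power remaining
#' after stage k is prod(1 - f_i, i <= k) and the cumulative loss is its
#' complement. An empty cascade loses nothing.
#'
#' @param loss_fractions Numeric vector of per-stage fractional losses, each in
#'   `[0, 1]`. Named entries label the stages.
#' @return A tibble with one row per stage (`stage`, `loss_fraction`,
#'   `remaining`, `cumulative_loss`); attributes `remaining` and
#'   `cumulative_loss` hold the final values. Class `power_budget`.
#' @examples
#' cascade_power_budget(c(skin = 0.20, fat = 0.10, muscle = 0.30, bone = 0.50))
#' @export
cascade_power_budget <- function(loss_fractions) {
  if (length(loss_fractions) > 0 &&
      (any(!is.finite(loss_fractions)) ||
       any(loss_fractions < 0) || any(loss_fractions > 1)))
    abort("All loss fractions must lie in [0, 1].")
  rem <- cumprod(1 - as.numeric(loss_fractions))
  stages <- names(loss_fractions) %||% as.character(seq_along(loss_fractions))
  out <- tibble(
    stage = stages,
    loss_fraction = as.numeric(loss_fractions),
    remaining = rem,
    cumulative_loss = 1 - rem
  )
  attr(out, "remaining") <- if (length(rem)) rem[length(rem)] else 1
  attr(out, "cumulative_loss") <- 1 - attr(out, "remaining")
  class(out) <- c("power_budget", class(out))
  out
}

#' @export
glance.power_budget <- function(x, ...) {
  tibble(
    n_stages = nrow(x),
    remaining = attr(x, "remaining"),
    cumulative_loss = attr(x, "cumulative_loss")
  )
}

#' Received-power contrast between a healthy and a fractured stack
#'
#' Runs [cascade_power_budget()] on both stacks and returns
#' `remaining(healthy) - remaining(fractured)` in percentage points. In the
#' full-replacement scenario (the bone stage's 50% loss replaced by blood's
#' 85%) this is about 17.5 points.
#'
#' @param healthy,fractured Loss-fraction vectors as in
#'   [cascade_power_budget()].
#' @return Difference in received power, percentage points.
#' @examples
#' healthy_vs_fractured_contrast(c(.2, .1, .3, .5), c(.2, .1, .3, .85))
#' @export
healthy_vs_fractured_contrast <- function(healthy, fractured) {
  rh <- attr(cascade_power_budget(healthy), "remaining")
  rf <- attr(cascade_power_budget(fractured), "remaining")
  100 * (rh - rf)
}

#' Refraction angle across a dielectric interface
#'
#' Snell's law for non-magnetic media in terms of relative permittivities:
#' sin(theta_t) = sqrt(eps1/eps2) * sin(theta_i). When the right-hand side
#' exceeds 1 the wave is totally internally reflected; this is signalled in the
#' `tir` column (with `theta_t_deg = NA`), not as an error.
#'
#' @param eps1,eps2 Relative permittivities of the incident and transmitting
#'   media, each >= 1.
#' @param theta_i_deg Incidence angle in degrees, in `[0, 90)`. Vectorised.
#' @return A tibble with columns `theta_i_deg`, `theta_t_deg`, `tir`.
#' @examples
#' snell_refraction(38, 5.28, 10)   # ~27.8 deg, bending away from normal
#' snell_refraction(5.28, 38, 30)   # ~10.7 deg, bending toward normal
#' @export
snell_refraction <- function(eps1, eps2, theta_i_deg) {
  if (any(eps1 < 1) || any(eps2 < 1)) abort("Permittivities must be >= 1.")
  if (any(theta_i_deg < 0) || any(theta_i_deg >= 90))
    abort("`theta_i_deg` must lie in [0, 90).")
  s <- sqrt(eps1 / eps2) * sin(theta_i_deg * pi / 180)
  tir <- s > 1
  theta_t <- ifelse(tir, NA_real_, asin(pmin(s, 1)) * 180 / pi)
  tibble(theta_i_deg = theta_i_deg, theta_t_deg = theta_t, tir = tir)
}

# Accept a tissue_tbl row-set or character names; always return a tibble.
resolve_tissue <- function(tissue, registry) {
  if (is.character(tissue)) {
    rows <- map(tissue, get_tissue, registry = registry)
    return(bind_rows(rows))
  }
  if (is.data.frame(tissue)) {
    required <- c("tissue", "eps_real", "sigma", "thickness_mm")
    missing <- setdiff(required, names(tissue))
    if (length(missing))
      abort(paste0("Tissue table lacks column(s): ",
                   paste(missing, collapse = ", "), "."))
    return(as_tibble(tissue))
  }
  abort("`tissue` must be a tissue tibble or a character vector of names.")
}
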