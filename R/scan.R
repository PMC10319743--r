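# Ray-based forward model of the dual-polarized raster scan.

#' Raster-scan grid
#'
#' Either a named preset — `"sim"`: 9 longitudinal steps over -70..70 mm by 7
#' rotational steps over -30..30 degrees (63 positions); `"meas"`: 5 steps
#' over -60..60 mm by 5 over -40..40 degrees (25 positions) — or explicit
#' strictly increasing position vectors.
#'
#' @param preset `"sim"` or `"meas"`, or `NULL` when giving explicit vectors.
#' @param d_mm Longitudinal positions (mm), strictly increasing.
#' @param alpha_deg Rotation angles (degrees), strictly increasing.
#' @param pol Polarizations, subset of `c("x", "y")`.
#' @return A `scan_grid` list with `d_mm`, `alpha_deg`, `pol`.
#' @examples
#' scan_grid("sim")
#' scan_grid(d_mm = seq(-40, 40, 20), alpha_deg = c(-10, 0, 10), pol = "y")
#' @export
scan_grid <- function(preset = NULL, d_mm = NULL, alpha_deg = NULL,
                      pol = c("x", "y")) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sim", "meas"))
    d_mm <- switch(preset, sim = seq(-70, 70, length.out = 9),
                   meas = seq(-60, 60, length.out = 5))
    alpha_deg <- switch(preset, sim = seq(-30, 30, length.out = 7),
                        meas = seq(-40, 40, length.out = 5))
  }
  if (is.null(d_mm) || is.null(alpha_deg) || !length(d_mm) || !length(alpha_deg))
    abort("Provide a preset or non-empty `d_mm` and `alpha_deg`.")
  if (any(diff(d_mm) <= 0) || (length(alpha_deg) > 1 && any(diff(alpha_deg) <= 0)))
    abort("Position lists must be strictly increasing.")
  pol <- match.arg(pol, c("x", "y"), several.ok = TRUE)
  structure(list(d_mm = d_mm, alpha_deg = alpha_deg, pol = pol),
            class = "scan_grid")
}

#' Polarization-weighted crack interaction strength
#'
#' How strongly the sensor at scan position (d, alpha) interacts with the
#' crack, in `[0, 1]`: the overlap of a Gaussian beam footprint (FWHM
#' `fwhm_mm`, the patch aperture size, in both the axial and arc-length
#' directions) with the crack's extent, multiplied by a polarization coupling
#' factor kappa. The incident E-field couples fully (kappa = 1) when
#' tangential to the crack's long axis, residually (`kappa_perp`) when
#' perpendicular, and with a `|cos|`/`|sin|` blend (floored at `kappa_perp`)
#' for inclined cracks so both polarizations respond. A transverse crack spans
#' the full bone cross-section (blood disc), so its overlap depends on d only.
#'
#' @param crack A [crack_spec()].
#' @param d_mm,alpha_deg Sensor position (vectorised, recycled).
#' @param pol `"x"` (E along the bone axis) or `"y"` (E azimuthal).
#' @param phantom Phantom providing the surface radius that converts azimuth
#'   to arc length.
#' @param fwhm_mm Beam footprint FWHM (mm).
#' @param kappa_perp Residual perpendicular coupling.
#' @return Numeric weights in `[0, 1]`.
#' @export
crack_interaction_weight <- function(crack, d_mm, alpha_deg, pol,
                                     phantom = arm_phantom(),
                                     fwhm_mm = 28, kappa_perp = 0.05) {
  stopifnot(inherits(crack, "crack_spec"))
  pol <- match.arg(pol, c("x", "y"))
  sig <- fwhm_mm / (2 * sqrt(2 * log(2)))
  r_surf <- phantom$radii_mm[["skin"]]
  n_pos <- max(length(d_mm), length(alpha_deg))
  d_mm <- rep_len(d_mm, n_pos)
  s <- r_surf * rep_len(alpha_deg, n_pos) * pi / 180  # sensor arc length
  s0 <- r_surf * crack$center_alpha_deg * pi / 180
  th <- crack$angle_deg * pi / 180            # 0 = transverse, 90 = longitudinal
  half <- crack$extent_mm / 2
  if (crack$orientation == "transverse") {
    # blood disc: azimuth-independent, centred at d0
    geom <- exp(-(d_mm - crack$center_d_mm)^2 / (2 * sig^2))
  } else {
    # centreline segment in (d, arc) space: t in [-half, half]
    tt <- seq(-half, half, length.out = 41L)
    dc <- crack$center_d_mm + tt * sin(th)
    sc <- s0 + tt * cos(th)
    geom <- map_dbl(seq_len(n_pos), function(i)
      max(exp(-((d_mm[i] - dc)^2 + (s[i] - sc)^2) / (2 * sig^2))))
  }
  kappa <- switch(pol,
    y = max(kappa_perp, abs(cos(th))),
    x = max(kappa_perp, abs(sin(th)))
  )
  geom * kappa
}

#' Forward-modelled transmission coefficient at one scan position
#'
#' Ray surrogate for the transceiver's through-tissue transmission: the
#' diametric path's per-segment complex propagation factors are multiplied,
#' `S21 = G0 prod(exp(-(alpha_i + j beta_i) L_i))`, with a crack-weighted
#' length of bone (`w_eff = width x interaction weight`, capped at the bone
#' diameter) replaced by the crack's fill tissue. `G0` is a fixed real
#' lens/antenna insertion factor. The companion `S11` is the air-skin
#' normal-incidence Fresnel reflection scaled by the same insertion factor
#' (plumbing so datasets carry both ports; the imaging chain uses S21 only).
#'
#' @param phantom An [arm_phantom()] (its `crack`, if any, is used).
#' @param d_mm,alpha_deg Sensor position.
#' @param pol `"x"` or `"y"`.
#' @param freq Frequency (Hz).
#' @param g0 Insertion factor in (0, 1].
#' @param fwhm_mm,kappa_perp Passed to [crack_interaction_weight()].
#' @return Complex S21 (scalar).
#' @export
simulate_s21 <- function(phantom, d_mm = 0, alpha_deg = 0, pol = "y",
                         freq = 2.45e9, g0 = 0.5, fwhm_mm = 28,
                         kappa_perp = 0.05) {
  stopifnot(inherits(phantom, "arm_phantom"))
  path <- diametric_path(phantom)
  lengths <- path$length_mm
  if (!is.null(phantom$crack)) {
    wt <- crack_interaction_weight(phantom$crack, d_mm, alpha_deg, pol,
                                   phantom, fwhm_mm, kappa_perp)
    bone_i <- which(path$tissue == "bone")
    w_eff <- min(phantom$crack$width_mm * wt, lengths[bone_i])
    lengths[bone_i] <- lengths[bone_i] - w_eff
    fill <- resolve_tissue(phantom$crack$fill, phantom$tissues)
    path <- bind_rows(path, fill %>% mutate(length_mm = NA_real_))
    lengths <- c(lengths, w_eff)
  }
  gam <- map_vec_c(seq_len(nrow(path)), function(i)
    propagation_constants(path[i, , drop = FALSE], freq)$gamma)
  g0 * prod(exp(-gam * lengths / 1000))
}

# Fresnel normal-incidence air->skin reflection used for the S11 column.
baseline_s11 <- function(phantom, g0 = 0.5) {
  eps_skin <- get_tissue("skin", phantom$tissues)$eps_real
  g0 * (1 - sqrt(eps_skin)) / (1 + sqrt(eps_skin))
}

#' Raster scan of an arm phantom
#'
#' Sweeps the transceiver over the grid and records one complex S-parameter
#' pair per (d, alpha, polarization, frequency). Optional measurement noise is
#' additive Gaussian on the amplitude in dB and on the phase in degrees,
#' independent per record and reproducible given `seed`.
#'
#' @param phantom An [arm_phantom()].
#' @param grid A [scan_grid()].
#' @param freqs Frequencies (Hz).
#' @param noise_sd_amp_db,noise_sd_phase_deg Noise standard deviations (0 =
#'   noise-free).
#' @param seed Integer seed for the noise draw (ignored when noise-free).
#' @param ... Forward-model parameters shared with [simulate_s21()]: `g0`,
#'   `fwhm_mm`, `kappa_perp`.
#' @return A `scan_dataset` tibble with columns `d_mm`, `alpha_deg`, `pol`,
#'   `freq_hz`, `s11`, `s21` (complex); attributes record the grid, seed and
#'   model version.
#' @examples
#' scans <- raster_scan(arm_phantom(crack = crack_spec()), scan_grid("sim"))
#' nrow(scans)  # 63 positions x 2 polarizations
#' @export
raster_scan <- function(phantom, grid = scan_grid("sim"), freqs = 2.45e9,
                        noise_sd_amp_db = 0, noise_sd_phase_deg = 0,
                        seed = NULL, ...) {
  stopifnot(inherits(phantom, "arm_phantom"), inherits(grid, "scan_grid"))
  dots <- list(...)
  g0 <- dots$g0 %||% 0.5
  fwhm_mm <- dots$fwhm_mm %||% 28
  kappa_perp <- dots$kappa_perp %||% 0.05
  recs <- tidyr::expand_grid(
    d_mm = grid$d_mm, alpha_deg = grid$alpha_deg, pol = grid$pol,
    freq_hz = freqs
  )
  # per-frequency baseline product once; vectorised crack substitution per
  # record (identical algebra to simulate_s21, which serves as the
  # per-position reference implementation)
  path <- diametric_path(phantom)
  bone_len <- path$length_mm[path$tissue == "bone"][1]
  s21 <- rep(NA_complex_, nrow(recs))
  for (f in unique(recs$freq_hz)) {
    gam <- map_vec_c(seq_len(nrow(path)), function(i)
      propagation_constants(path[i, , drop = FALSE], f)$gamma)
    base <- g0 * prod(exp(-gam * path$length_mm / 1000))
    idx <- which(recs$freq_hz == f)
    if (is.null(phantom$crack)) {
      s21[idx] <- base
    } else {
      gam_bone <- propagation_constants("bone", f, phantom$tissues)$gamma
      gam_fill <- propagation_constants(
        resolve_tissue(phantom$crack$fill, phantom$tissues), f)$gamma
      for (p in unique(recs$pol[idx])) {
        ip <- idx[recs$pol[idx] == p]
        wt <- crack_interaction_weight(phantom$crack, recs$d_mm[ip],
                                       recs$alpha_deg[ip], p, phantom,
                                       fwhm_mm, kappa_perp)
        w_eff <- pmin(phantom$crack$width_mm * wt, bone_len)
        s21[ip] <- base * exp((gam_bone - gam_fill) * w_eff / 1000)
      }
    }
  }
  s11 <- rep(as.complex(baseline_s11(phantom, g0)), nrow(recs))
  if (noise_sd_amp_db > 0 || noise_sd_phase_deg > 0) {
    noise <- with_local_seed(seed, list(
      amp_db = rnorm(nrow(recs), 0, noise_sd_amp_db),
      ph_deg = rnorm(nrow(recs), 0, noise_sd_phase_deg)
    ))
    mag <- pmin(Mod(s21) * 10^(noise$amp_db / 20), 1)  # keep passive
    s21 <- complex(modulus = mag,
                   argument = Arg(s21) + noise$ph_deg * pi / 180)
  }
  out <- recs %>% mutate(s11 = s11, s21 = s21)
  class(out) <- c("scan_dataset", class(out))
  attr(out, "grid") <- grid
  attr(out, "seed") <- seed
  attr(out, "model_version") <- as.character(utils::packageVersion("bonewave"))
  attr(out, "phantom_hash") <- rlang::hash(phantom)
  out
}

#' Restrict a scan dataset to one frequency
#'
#' Selects the stored frequency nearest to `f0` (exact match preferred; a
#' warning reports approximate matches).
#'
#' @param dataset A `scan_dataset`.
#' @param f0 Target frequency (Hz).
#' @return The restricted dataset; attribute `selected_freq` reports the bin.
#' @export
sample_at_frequency <- function(dataset, f0 = 2.45e9) {
  if (!nrow(dataset)) abort("Empty scan dataset.")
  freqs <- sort(unique(dataset$freq_hz))
  sel <- freqs[which.min(abs(freqs - f0))]
  if (sel != f0)
    warn(paste0("No exact frequency bin at ", f0, " Hz; using nearest ",
                sel, " Hz."))
  out <- dataset %>% filter(.data$freq_hz == sel)
  for (a in c("grid", "seed", "model_version", "phantom_hash"))
    attr(out, a) <- attr(dataset, a)
  attr(out, "selected_freq") <- sel
  class(out) <- unique(c("scan_dataset", class(out)))
  out
}

# Evaluate expr with a locally-scoped RNG seed; global RNG state is restored.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
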