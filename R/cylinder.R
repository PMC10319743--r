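# Near-field mode matching for concentric lossy cylinders.
#
# Time convention e^{-i omega t}: H^(1)_n is the outgoing wave and lossy media
# have complex relative permittivity eps' + i sigma/(omega eps0) (note the
# opposite sign to the e^{+j omega t} scalar formulas in propagation.R).
# Fields per azimuthal harmonic n and axial wavenumber kz:
#   region I   (core):          (E_ax, H_ax) = A_1 J_n(k_1r r)
#   region II  (annular layers): A_2i J_n(k_2ir r) + B_2i H^(1)_n(k_2ir r)
#   region III (exterior):       A_ext J_n (incident, given) + B_3 H^(1)_n
# with A, B 2-vectors (E_ax, H_ax components).

#' Concentric cylinder layer and stack
#'
#' `cyl_layer()` describes one concentric layer; `cyl_stack()` assembles
#' layers, ordered inner to outer, into a stack tibble. The innermost row is
#' the core (region I); the outermost row is the unbounded exterior
#' (region III, `outer_radius_mm = Inf`). At least two layers are required.
#'
#' @param outer_radius_mm Outer radius of the layer in mm (`Inf` for the
#'   exterior region).
#' @param eps_complex Complex relative permittivity under the e^{-i omega t}
#'   convention (lossy: positive imaginary part). A real number is accepted
#'   for lossless media.
#' @param mu Relative permeability (default 1).
#' @param label Optional layer label.
#' @return A one-row tibble (`cyl_layer`) or a stack tibble (`cyl_stack`).
#' @examples
#' cyl_stack(
#'   cyl_layer(15, 11.4 + 0.57i, label = "bone"),
#'   cyl_layer(Inf, 1, label = "air")
#' )
#' @export
cyl_layer <- function(outer_radius_mm, eps_complex, mu = 1, label = NA_character_) {
  eps_complex <- as.complex(eps_complex)
  if (Re(eps_complex) < 0) abort("Re(eps_complex) must be >= 0.")
  tibble(
    label = label, outer_radius_mm = outer_radius_mm,
    eps_complex = eps_complex, mu = mu
  )
}

#' @rdname cyl_layer
#' @param ... `cyl_layer()` rows (or a single tibble of them), inner to outer.
#' @export
cyl_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.data.frame(layers[[1]]) &&
      nrow(layers[[1]]) > 1L) {
    stack <- as_tibble(layers[[1]])
  } else {
    stack <- bind_rows(layers)
  }
  if (nrow(stack) < 2L) abort("A stack needs at least core + exterior layers.")
  r <- stack$outer_radius_mm
  if (!is.infinite(r[length(r)]))
    abort("The outermost layer must be unbounded (outer_radius_mm = Inf).")
  finite_r <- r[-length(r)]
  if (any(!is.finite(finite_r)) || any(finite_r <= 0) ||
      any(diff(finite_r) <= 0))
    abort("Interface radii must be positive and strictly increasing outward.")
  class(stack) <- c("cyl_stack", class(stack))
  stack
}

#' Arm-phantom cylinder stack
#'
#' Builds the five-region bone/muscle/fat/skin/air stack from an arm phantom
#' description, converting each tissue's conductivity to a complex
#' permittivity at `freq` under the e^{-i omega t} convention.
#'
#' @param phantom An [arm_phantom()]; its layer radii and tissue table are
#'   used.
#' @param freq Frequency in Hz.
#' @return A `cyl_stack` tibble (bone core, muscle, fat, skin annuli, air
#'   exterior).
#' @export
arm_stack <- function(phantom = arm_phantom(), freq = 2.45e9) {
  w <- 2 * pi * freq
  eps_c <- function(tis) {
    row <- get_tissue(tis, phantom$tissues)
    complex(real = row$eps_real, imaginary = row$sigma / (w * .eps0))
  }
  cyl_stack(
    cyl_layer(phantom$radii_mm[["bone"]], eps_c("bone"), label = "bone"),
    cyl_layer(phantom$radii_mm[["muscle"]], eps_c("muscle"), label = "muscle"),
    cyl_layer(phantom$radii_mm[["fat"]], eps_c("fat"), label = "fat"),
    cyl_layer(phantom$radii_mm[["skin"]], eps_c("skin"), label = "skin"),
    cyl_layer(Inf, 1 + 0i, label = "air")
  )
}

#' Cylindrical mode specification
#'
#' @param n Azimuthal harmonic order, integer >= 0.
#' @param kz Axial wavenumber in rad/m (default 0: normal incidence on an
#'   infinite cylinder).
#' @param freq Frequency in Hz, > 0.
#' @return A `mode_spec` list.
#' @export
mode_spec <- function(n = 0L, kz = 0, freq = 2.45e9) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    abort("`n` must be a single integer >= 0.")
  if (!is.numeric(freq) || freq <= 0) abort("`freq` must be > 0.")
  structure(list(n = as.integer(n), kz = kz, freq = freq),
            class = "mode_spec")
}

#' Radial wavenumber of a layer for a given mode
#'
#' k_r = sqrt(omega^2 mu eps - kz^2) on the branch with Im(k_r) >= 0, so the
#' outgoing Hankel wave decays in lossy media under e^{-i omega t}. Evanescent
#' modes (kz beyond the medium wavenumber) return a positive imaginary k_r
#' rather than an error.
#'
#' @param layer A one-row [cyl_layer()] tibble.
#' @param mode A [mode_spec()].
#' @return Complex k_r in rad/m.
#' @export
radial_wavenumber <- function(layer, mode) {
  stopifnot(inherits(mode, "mode_spec"))
  w <- 2 * pi * mode$freq
  k2 <- w^2 * .mu0 * layer$mu * .eps0 * layer$eps_complex - mode$kz^2
  kr <- sqrt(k2)
  if (Im(kr) < 0) kr <- -kr
  if (Im(kr) == 0 && Re(kr) < 0) kr <- -kr
  kr
}

# Eq.-style 2x2 modal matrix mapping an amplitude 2-vector (E_ax, H_ax) to the
# tangential pair (r*H_phi, r*E_phi), for Bessel (kind = "J") or outgoing
# Hankel (kind = "H") radial dependence. r in meters; eps, mu absolute.
modal_matrix <- function(mode, layer, r_m, kind = c("J", "H")) {
  kind <- match.arg(kind)
  kr <- radial_wavenumber(layer, mode)
  w <- 2 * pi * mode$freq
  k_med <- w * sqrt(.mu0 * layer$mu * .eps0 * Mod(layer$eps_complex))
  if (Mod(kr) < 1e-7 * k_med)
    abort("k_r = 0: the modal matrix is undefined for this degenerate (cutoff) mode.")
  eps <- .eps0 * layer$eps_complex
  mu <- .mu0 * layer$mu
  x <- kr * r_m
  n <- mode$n
  if (kind == "J") {
    zn <- bw_J(n, x); znp <- bw_Jp(n, x)
  } else {
    zn <- bw_H1(n, x); znp <- bw_H1p(n, x)
  }
  off <- -n * mode$kz * zn
  matrix(c(1i * w * eps * x * znp, off,
           off, -1i * w * mu * x * znp), 2, 2, byrow = TRUE) / kr^2
}

#' Modal coupling matrices of a cylindrical layer
#'
#' The 2x2 matrices that map a harmonic's axial amplitude 2-vector
#' (E_ax, H_ax) to the tangential field pair (r H_phi, r E_phi) at radius `r`:
#' diagonal entries proportional to `+i omega eps k_r r Z'_n` and
#' `-i omega mu k_r r Z'_n`, off-diagonal entries `-n kz Z_n` (identical to
#' each other), all scaled by 1/k_r^2. `modal_matrix_J()` uses the standing
#' (Bessel) radial dependence, `modal_matrix_H()` the outgoing Hankel one.
#' For n = 0 or kz = 0 the off-diagonal entries vanish and the TE/TM channels
#' decouple.
#'
#' @inheritParams radial_wavenumber
#' @param r_mm Evaluation radius in mm, > 0.
#' @return A 2x2 complex matrix.
#' @export
modal_matrix_J <- function(mode, layer, r_mm) {
  if (r_mm <= 0) abort("`r_mm` must be > 0.")
  modal_matrix(mode, layer, r_mm / 1000, "J")
}

#' @rdname modal_matrix_J
#' @export
modal_matrix_H <- function(mode, layer, r_mm) {
  if (r_mm <= 0) abort("`r_mm` must be > 0.")
  modal_matrix(mode, layer, r_mm / 1000, "H")
}

#' Interface transmission and reflection matrices
#'
#' The 2x2 transmission and reflection matrices of the boundary between an
#' inner layer i and outer layer j at radius `a`:
#' \deqn{\bar T_{ij} = \frac{2\omega}{\pi k_{ir}^2 a} \bar D^{-1}
#'   \mathrm{diag}(\varepsilon_i, -\mu_i), \qquad
#'   \bar D = \bar J_n(k_{ir} a) H^{(1)}_n(k_{jr} a) -
#'            J_n(k_{ir} a) \bar H^{(1)}_n(k_{jr} a),}
#' and analogously for the reverse direction and the reflection matrices
#' (Hankel-pair bracket for R_ij, Bessel-pair bracket for R_ji). For identical
#' media the reflection brackets cancel term by term, giving exact zero
#' matrices, and the Wronskian collapses D to a diagonal; with the
#' conventional 2 omega / (pi k^2 a) prefactor the identical-media
#' transmission matrix is then (1/a) times the identity — a pure normalization
#' of the per-layer amplitude bookkeeping (the amplitude solver in
#' [solve_amplitudes()] enforces raw field continuity and is unaffected by
#' this choice).
#'
#' @param inner,outer One-row [cyl_layer()] tibbles on either side of the
#'   boundary.
#' @param a_mm Shared boundary radius in mm.
#' @param mode A [mode_spec()].
#' @return List with 2x2 complex matrices `T_io`, `T_oi`, `R_io`, `R_oi` and
#'   the boundary matrix `D`.
#' @export
interface_matrices <- function(inner, outer, a_mm, mode) {
  a <- a_mm / 1000
  ki <- radial_wavenumber(inner, mode)
  kj <- radial_wavenumber(outer, mode)
  w <- 2 * pi * mode$freq
  Ji_bar <- modal_matrix(mode, inner, a, "J")
  Hi_bar <- modal_matrix(mode, inner, a, "H")
  Jj_bar <- modal_matrix(mode, outer, a, "J")
  Hj_bar <- modal_matrix(mode, outer, a, "H")
  Ji <- bw_J(mode$n, ki * a); Hi <- bw_H1(mode$n, ki * a)
  Jj <- bw_J(mode$n, kj * a); Hj <- bw_H1(mode$n, kj * a)
  D <- Ji_bar * Hj - Ji * Hj_bar
  dd <- D[1, 1] * D[2, 2] - D[1, 2] * D[2, 1]
  if (Mod(dd) <= 1e-14 * max(Mod(D))^2)
    abort("Singular boundary matrix D: degenerate (resonant) mode at this interface.")
  Dinv <- matrix(c(D[2, 2], -D[1, 2], -D[2, 1], D[1, 1]), 2, 2,
                 byrow = TRUE) / dd
  eps_i <- .eps0 * inner$eps_complex; mu_i <- .mu0 * inner$mu
  eps_j <- .eps0 * outer$eps_complex; mu_j <- .mu0 * outer$mu
  list(
    T_io = (2 * w / (pi * ki^2 * a)) * Dinv %*% diag(c(eps_i, -mu_i)),
    T_oi = (2 * w / (pi * kj^2 * a)) * Dinv %*% diag(c(eps_j, -mu_j)),
    R_io = Dinv %*% (Hi * Hj_bar - Hj * Hi_bar),
    R_oi = Dinv %*% (Ji * Jj_bar - Jj * Ji_bar),
    D = D
  )
}

# 4-vector of matched quantities (E_ax, H_ax, r H_phi, r E_phi) contributed by
# the standing (J) and outgoing (H) parts of a layer at radius r_m:
# returns list(MJ, MH): 4x2 complex matrices acting on the A and B 2-vectors.
continuity_blocks <- function(mode, layer, r_m) {
  kr <- radial_wavenumber(layer, mode)
  x <- kr * r_m
  jn <- bw_J(mode$n, x); hn <- bw_H1(mode$n, x)
  MJ <- rbind(diag(2) * jn, modal_matrix(mode, layer, r_m, "J"))
  MH <- rbind(diag(2) * hn, modal_matrix(mode, layer, r_m, "H"))
  list(MJ = MJ, MH = MH)
}

#' Solve modal amplitudes of a layered cylinder
#'
#' Given a unit-amplitude incoming standing wave in the exterior region
#' (per-harmonic excitation; plane-wave synthesis over harmonics is provided
#' by [solve_plane_wave()]), finds the amplitude 2-vectors in every layer by
#' enforcing continuity of the tangential fields (E_ax, H_ax, H_phi, E_phi) at
#' every interface. The core carries only the standing (Bessel) wave, the
#' exterior only the incident wave plus an outgoing (Hankel) wave; the block
#' linear system over all interfaces is assembled and solved directly with
#' column equilibration (at most 16 x 16 complex for the arm stack).
#'
#' @param stack A [cyl_stack()].
#' @param mode A [mode_spec()].
#' @param excitation Length-2 complex vector: incident standing-wave amplitude
#'   (E_ax, H_ax) in the exterior region. Default `c(1, 0)` (axial-E, i.e.
#'   TM-polarized excitation).
#' @return A `modal_amplitudes` tibble: one row per layer with columns
#'   `layer`, `label`, `region` (I/II/III), and complex `A_E`, `A_H` (standing)
#'   and `B_E`, `B_H` (outgoing) amplitudes. Attributes: `mode`, `stack`,
#'   `residual` (worst relative boundary mismatch).
#' @export
solve_amplitudes <- function(stack, mode, excitation = c(1, 0)) {
  stopifnot(inherits(stack, "cyl_stack"), inherits(mode, "mode_spec"))
  excitation <- as.complex(excitation)
  stopifnot(length(excitation) == 2L)
  L <- nrow(stack)
  n_ifc <- L - 1L
  a_m <- stack$outer_radius_mm[seq_len(n_ifc)] / 1000
  # unknown layout: core A1 (2) | per middle layer A_i, B_i (4) | exterior B (2)
  n_unk <- 4L * n_ifc
  col_of <- function(layer) {
    if (layer == 1L) list(A = 1:2, B = NULL)
    else if (layer == L) list(A = NULL, B = (n_unk - 1L):n_unk)
    else list(A = 4L * (layer - 2L) + 3:4, B = 4L * (layer - 2L) + 5:6)
  }
  M <- matrix(0 + 0i, n_unk, n_unk)
  rhs <- rep(0 + 0i, n_unk)
  for (m in seq_len(n_ifc)) {
    rows <- 4L * (m - 1L) + 1:4
    inner <- stack[m, , drop = FALSE]
    outer <- stack[m + 1L, , drop = FALSE]
    bi <- continuity_blocks(mode, inner, a_m[m])
    bo <- continuity_blocks(mode, outer, a_m[m])
    ci <- col_of(m); co <- col_of(m + 1L)
    if (!is.null(ci$A)) M[rows, ci$A] <- M[rows, ci$A] + bi$MJ
    if (!is.null(ci$B)) M[rows, ci$B] <- M[rows, ci$B] + bi$MH
    if (!is.null(co$A)) M[rows, co$A] <- M[rows, co$A] - bo$MJ
    if (!is.null(co$B)) M[rows, co$B] <- M[rows, co$B] - bo$MH
    if (m == n_ifc) {
      # exterior incident standing wave is known: move to the RHS
      rhs[rows] <- rhs[rows] + bo$MJ %*% excitation
    }
  }
  # column equilibration keeps tiny-J / huge-H high orders solvable
  cs <- apply(M, 2, function(col) max(Mod(col)))
  cs[cs == 0] <- 1
  y <- tryCatch(
    solve(sweep(M, 2, cs, "/"), rhs),
    error = function(e) abort(paste0(
      "Singular global mode-matching system (n = ", mode$n, "): ",
      conditionMessage(e)))
  )
  x <- y / cs
  amp <- function(layer) {
    cl <- col_of(layer)
    A <- if (is.null(cl$A)) excitation else x[cl$A]
    B <- if (is.null(cl$B)) c(0 + 0i, 0 + 0i) else x[cl$B]
    if (layer == 1L) B <- c(0 + 0i, 0 + 0i)
    list(A = A, B = B)
  }
  amps <- map(seq_len(L), amp)
  out <- tibble(
    layer = seq_len(L),
    label = stack$label,
    region = c("I", rep("II", max(L - 2L, 0L)), "III")[seq_len(L)],
    A_E = map_vec_c(amps, function(a) a$A[1]),
    A_H = map_vec_c(amps, function(a) a$A[2]),
    B_E = map_vec_c(amps, function(a) a$B[1]),
    B_H = map_vec_c(amps, function(a) a$B[2])
  )
  class(out) <- c("modal_amplitudes", class(out))
  attr(out, "mode") <- mode
  attr(out, "stack") <- stack
  attr(out, "residual") <- boundary_residual(out, stack, mode)
  out
}

map_vec_c <- function(x, f) vapply(x, f, complex(1))

# Worst relative mismatch of the four matched quantities over all interfaces.
boundary_residual <- function(amps, stack, mode) {
  L <- nrow(stack)
  worst <- 0
  for (m in seq_len(L - 1L)) {
    r_m <- stack$outer_radius_mm[m] / 1000
    vi <- layer_continuity_vector(amps, stack, mode, m, r_m)
    vo <- layer_continuity_vector(amps, stack, mode, m + 1L, r_m)
    scale <- max(Mod(c(vi, vo)), 1e-300)
    worst <- max(worst, max(Mod(vi - vo)) / scale)
  }
  worst
}

layer_continuity_vector <- function(amps, stack, mode, layer, r_m) {
  b <- continuity_blocks(mode, stack[layer, , drop = FALSE], r_m)
  A <- c(amps$A_E[layer], amps$A_H[layer])
  B <- c(amps$B_E[layer], amps$B_H[layer])
  as.vector(b$MJ %*% A + b$MH %*% B)
}

#' Axial fields of a solved cylinder mode
#'
#' Evaluates (E_ax, H_ax) at the requested radii: Bessel-only in the core
#' (finite at r = 0), Bessel + Hankel in annular layers, incident + outgoing
#' Hankel in the exterior. Radii falling exactly on an interface are evaluated
#' from the inner side.
#'
#' @param amps A `modal_amplitudes` result from [solve_amplitudes()].
#' @param r_mm Radii in mm, >= 0 (vectorised).
#' @return A tibble with columns `r_mm`, `layer`, `label`, `E_ax`, `H_ax`
#'   (complex).
#' @export
axial_fields <- function(amps, r_mm) {
  stopifnot(inherits(amps, "modal_amplitudes"))
  stack <- attr(amps, "stack")
  mode <- attr(amps, "mode")
  if (any(r_mm < 0)) abort("`r_mm` must be >= 0.")
  n <- mode$n
  rows <- map(r_mm, function(r) {
    # interface radii belong to the inner layer
    li <- which(r <= stack$outer_radius_mm)[1]
    kr <- radial_wavenumber(stack[li, , drop = FALSE], mode)
    x <- kr * r / 1000
    A <- c(amps$A_E[li], amps$A_H[li])
    B <- c(amps$B_E[li], amps$B_H[li])
    jn <- if (r == 0 && n > 0) 0 + 0i else bw_J(n, x)
    f <- A * jn
    if (any(B != 0)) f <- f + B * bw_H1(n, x)
    tibble(r_mm = r, layer = li, label = stack$label[li],
           E_ax = f[1], H_ax = f[2])
  })
  list_rbind(rows)
}

#' Time-averaged radial power flux through a cylindrical surface
#'
#' Per-harmonic, per-unit-length net radial Poynting flux
#' `P(r) = pi r Re(E_phi conj(H_ax) - E_ax conj(H_phi))` at radius `r`. In an
#' all-lossless stack P(r) is independent of r between interfaces (energy
#' conservation), which the tests verify.
#'
#' @inheritParams axial_fields
#' @return A tibble with `r_mm`, `flux` (net radial power, W/m at the solver's
#'   amplitude normalisation) and `scale`, the corresponding unsigned power
#'   magnitude `pi (|r E_phi||H_ax| + |E_ax||r H_phi|)` against which a
#'   conservation residual should be measured (a standing-wave-dominated
#'   solution has net flux near zero while `scale` stays finite).
#' @export
radial_power_flux <- function(amps, r_mm) {
  stopifnot(inherits(amps, "modal_amplitudes"))
  stack <- attr(amps, "stack")
  mode <- attr(amps, "mode")
  rows <- map(r_mm, function(r) {
    li <- which(r <= stack$outer_radius_mm)[1]
    r_m <- r / 1000
    v <- layer_continuity_vector(amps, stack, mode, li, r_m)
    # v = (E_ax, H_ax, r H_phi, r E_phi)
    tibble(
      r_mm = r,
      flux = pi * Re(v[4] * Conj(v[2]) - v[1] * Conj(v[3])),
      scale = pi * (Mod(v[4]) * Mod(v[2]) + Mod(v[1]) * Mod(v[3]))
    )
  })
  list_rbind(rows)
}

#' Local reflection coefficient seen by the exterior standing wave
#'
#' Decomposing the exterior standing wave J_n = (H^(1) + H^(2))/2 into
#' incoming and outgoing parts, the outgoing/incoming amplitude ratio in the
#' excited channel is 1 + 2 B / A. For a boundary radius much larger than the
#' wavelength this converges (in magnitude) to the planar Fresnel
#' normal-incidence reflection coefficient of the interface.
#'
#' @param amps A `modal_amplitudes` result.
#' @param channel `"E"` (axial-E / TM) or `"H"` (axial-H / TE).
#' @return Complex reflection coefficient.
#' @export
cylinder_reflection <- function(amps, channel = c("E", "H")) {
  channel <- match.arg(channel)
  L <- nrow(amps)
  A <- if (channel == "E") amps$A_E[L] else amps$A_H[L]
  B <- if (channel == "E") amps$B_E[L] else amps$B_H[L]
  if (Mod(A) == 0) abort("No incident amplitude in the requested channel.")
  1 + 2 * B / A
}

#' Default harmonic truncation order
#'
#' `max(10, ceil(k a_outer) + 8)` with k the exterior wavenumber and a_outer
#' the outermost interface radius.
#'
#' @param stack A [cyl_stack()].
#' @param freq Frequency in Hz.
#' @return Integer truncation order N (harmonics 0..N).
#' @export
n_max_default <- function(stack, freq = 2.45e9) {
  L <- nrow(stack)
  k <- 2 * pi * freq / .c0 * sqrt(Mod(stack$eps_complex[L] * stack$mu[L]))
  a <- max(stack$outer_radius_mm[seq_len(L - 1L)]) / 1000
  as.integer(max(10, ceiling(k * a) + 8))
}

#' Plane-wave scattering synthesis over harmonics
#'
#' Expands a unit plane wave incident on the cylinder axis into cylindrical
#' harmonics with Jacobi-Anger weights i^n (axial-E polarization) and solves
#' each harmonic with [solve_amplitudes()]. Convergence of the exterior
#' scattered amplitude across the truncation order is reported.
#'
#' @param stack A [cyl_stack()].
#' @param freq Frequency in Hz.
#' @param n_max Truncation order; default [n_max_default()].
#' @param kz Axial wavenumber (rad/m).
#' @return A tibble with one row per harmonic `n`: weight, scattered exterior
#'   amplitude `B_E`, solver `residual`, and `converged` flag on the tail
#'   harmonic magnitudes.
#' @export
solve_plane_wave <- function(stack, freq = 2.45e9, n_max = NULL, kz = 0) {
  n_max <- n_max %||% n_max_default(stack, freq)
  rows <- map(0:n_max, function(n) {
    md <- mode_spec(n = n, kz = kz, freq = freq)
    sol <- solve_amplitudes(stack, md, excitation = c(1, 0))
    L <- nrow(sol)
    tibble(n = n, weight = (1i)^n, B_E = sol$B_E[L],
           residual = attr(sol, "residual"))
  })
  out <- list_rbind(rows)
  tail_mag <- Mod(out$B_E[nrow(out)])
  peak <- max(Mod(out$B_E))
  out$converged <- tail_mag <= 1e-6 * max(peak, 1e-300)
  out
}
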