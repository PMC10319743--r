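# Cylindrical multilayer mode matching: wavenumbers, modal matrices,
# interface matrices, amplitude solves and their physical oracles.

f0 <- 2.45e9
lam_mm <- 1000 * 299792458 / f0

test_that("radial wavenumber branch: lossless, cutoff, lossy", {
  lossless <- cyl_layer(10, 4 + 0i)
  k <- radial_wavenumber(lossless, mode_spec(n = 0, kz = 0, freq = f0))
  k_expect <- 2 * pi * f0 / 299792458 * 2
  expect_equal(Re(k), k_expect, tolerance = 1e-8)
  expect_identical(Im(k), 0)
  # kz at the medium wavenumber: radial cutoff (k_r collapses by >4 orders)
  expect_lt(Mod(radial_wavenumber(lossless,
                                  mode_spec(n = 0, kz = Re(k), freq = f0))),
            1e-4 * k_expect)
  # evanescent: kz beyond the wavenumber gives positive-imaginary k_r
  kev <- radial_wavenumber(lossless, mode_spec(n = 0, kz = 2 * k_expect,
                                               freq = f0))
  expect_gt(Im(kev), 0)
  expect_equal(Re(kev), 0, tolerance = 1e-9)
  # skin at 2.45 GHz: Re(k_r) near the lossless omega sqrt(eps')/c, Im > 0
  skin <- cyl_layer(27, 38 + 10.72637i)
  ks <- radial_wavenumber(skin, mode_spec(n = 0, kz = 0, freq = f0))
  expect_equal(Re(ks), 51.3482 * sqrt(38), tolerance = 0.02)
  expect_gt(Im(ks), 0)
})

test_that("modal matrices have the required structure", {
  layer <- cyl_layer(10, 7 + 0.5i)
  # off-diagonals vanish when n = 0 or kz = 0; equal to each other otherwise
  m0 <- modal_matrix_J(mode_spec(n = 0, kz = 40, freq = f0), layer, 8)
  expect_identical(m0[1, 2], 0 + 0i)
  expect_identical(m0[2, 1], 0 + 0i)
  mk <- modal_matrix_J(mode_spec(n = 3, kz = 0, freq = f0), layer, 8)
  expect_identical(mk[1, 2], 0 + 0i)
  m <- modal_matrix_H(mode_spec(n = 3, kz = 55, freq = f0), layer, 8)
  expect_identical(m[1, 2], m[2, 1])
  expect_error(
    modal_matrix_J(mode_spec(n = 0,
                             kz = Re(radial_wavenumber(
                               cyl_layer(10, 4 + 0i),
                               mode_spec(0, 0, f0))) * 1,
                             freq = f0),
                   cyl_layer(10, 4 + 0i), 8),
    "k_r = 0")
})

test_that("modal matrix spot value matches a direct special-function build", {
  md <- mode_spec(n = 1, kz = 30, freq = f0)
  layer <- cyl_layer(20, 5 + 0.4i)
  kr <- radial_wavenumber(layer, md)
  r_mm <- Re(2 / kr) * 1000  # real k_r * r close to 2
  got <- modal_matrix_J(md, layer, r_mm)
  # independent assembly from the series-backed primitives
  w <- 2 * pi * f0
  eps <- 8.8541878128e-12 * (5 + 0.4i); mu <- 4e-7 * pi
  x <- kr * r_mm / 1000
  jn <- bonewave:::bw_J(1L, x); jnp <- bonewave:::bw_Jp(1L, x)
  want <- matrix(c(1i * w * eps * x * jnp, -1 * 30 * jn,
                   -1 * 30 * jn, -1i * w * mu * x * jnp), 2, 2,
                 byrow = TRUE) / kr^2
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("identical-media interfaces are exact no-ops", {
  md <- mode_spec(n = 2, kz = 25, freq = f0)
  same <- cyl_layer(12, 6 + 0.8i)
  im <- interface_matrices(same, same, 12, md)
  expect_identical(max(Mod(im$R_io)), 0)
  expect_identical(max(Mod(im$R_oi)), 0)
  # Wronskian collapses D to a diagonal; the round-trip transmission is a
  # scalar multiple of the identity (1/a^2 with the verbatim prefactor)
  rt <- im$T_oi %*% im$T_io
  expect_equal(rt[1, 2], 0 + 0i, tolerance = 1e-16)
  expect_equal(rt[2, 1], 0 + 0i, tolerance = 1e-16)
  expect_equal(rt[1, 1], rt[2, 2], tolerance = 1e-10)
  expect_equal(Mod(rt[1, 1]), 1 / 0.012^2, tolerance = 1e-8)
  # TE/TM decoupling: all four matrices diagonal at kz = 0, n = 0
  im0 <- interface_matrices(cyl_layer(12, 6 + 0.8i), cyl_layer(Inf, 1 + 0i),
                            12, mode_spec(n = 0, kz = 0, freq = f0))
  for (M in im0[c("T_io", "T_oi", "R_io", "R_oi")]) {
    expect_identical(M[1, 2], 0 + 0i)
    expect_identical(M[2, 1], 0 + 0i)
  }
})

test_that("single-medium stack passes the excitation through unscattered", {
  st <- cyl_stack(cyl_layer(15, 4 + 0i), cyl_layer(30, 4 + 0i),
                  cyl_layer(Inf, 4 + 0i))
  md <- mode_spec(n = 1, kz = 30, freq = f0)
  sol <- solve_amplitudes(st, md, excitation = c(1, 0.5i))
  # every layer carries the incident standing wave; no outgoing wave anywhere
  expect_equal(sol$A_E, rep(1 + 0i, 3), tolerance = 1e-12)
  expect_equal(sol$A_H, rep(0.5i, 3), tolerance = 1e-12)
  expect_equal(max(Mod(sol$B_E)), 0, tolerance = 1e-12)
  expect_equal(max(Mod(sol$B_H)), 0, tolerance = 1e-12)
  expect_lt(attr(sol, "residual"), 1e-12)
})

test_that("two-layer dielectric cylinder matches an independent continuity solve", {
  # TM (axial-E) scattering off a lossless dielectric cylinder in air,
  # n = 0..3, kz = 0: solve the decoupled 2x2 continuity system directly
  # from the scalar fields (independent of the solver's block assembly).
  a_mm <- 12
  eps_in <- 6.25
  st <- cyl_stack(cyl_layer(a_mm, eps_in + 0i), cyl_layer(Inf, 1 + 0i))
  w <- 2 * pi * f0
  k_out <- w / 299792458
  k_in <- k_out * sqrt(eps_in)
  a <- a_mm / 1000
  for (n in 0:3) {
    md <- mode_spec(n = n, kz = 0, freq = f0)
    sol <- solve_amplitudes(st, md, excitation = c(1, 0))
    J <- function(nn, x) bonewave:::bw_J(nn, x)
    H <- function(nn, x) bonewave:::bw_H1(nn, x)
    Jp <- function(nn, x) bonewave:::bw_Jp(nn, x)
    Hp <- function(nn, x) bonewave:::bw_H1p(nn, x)
    # unknowns (A_core, B_ext): Ez and H_phi (prop. to sqrt(eps) Z') continuity
    M <- matrix(c(
      J(n, k_in * a + 0i), -H(n, k_out * a + 0i),
      sqrt(eps_in) * Jp(n, k_in * a + 0i), -Hp(n, k_out * a + 0i)
    ), 2, 2, byrow = TRUE)
    rhs <- c(J(n, k_out * a + 0i), Jp(n, k_out * a + 0i))
    ref <- solve(M, rhs)
    expect_equal(sol$A_E[1], ref[1], tolerance = 1e-8)
    expect_equal(sol$B_E[2], ref[2], tolerance = 1e-8)
    # TE channel silent under pure axial-E excitation at kz = 0
    expect_equal(Mod(sol$B_H[2]), 0, tolerance = 1e-12)
    expect_lt(attr(sol, "residual"), 1e-8)
  }
})

test_that("large-radius boundary reproduces planar Fresnel reflection", {
  # absorbing half-space behind a boundary of radius >= 100 wavelengths:
  # the standing/outgoing decomposition's local reflection magnitude must
  # approach |(1 - n2)/(1 + n2)| (normal incidence, air outside)
  eps2 <- 4 + 0.2i
  n2 <- sqrt(eps2)
  fres <- Mod((1 - n2) / (1 + n2))
  a <- 100 * lam_mm
  for (n in 0:2) {
    st <- cyl_stack(cyl_layer(a, eps2), cyl_layer(Inf, 1 + 0i))
    sol <- solve_amplitudes(st, mode_spec(n = n, kz = 0, freq = f0))
    gam <- cylinder_reflection(sol, "E")
    expect_lt(abs(Mod(gam) - fres) / fres, 0.01)
  }
})

test_that("lossless stacks conserve radial power flux", {
  st <- cyl_stack(cyl_layer(15, 9 + 0i), cyl_layer(25, 2.5 + 0i),
                  cyl_layer(Inf, 1 + 0i))
  sol <- solve_amplitudes(st, mode_spec(n = 1, kz = 20, freq = f0),
                          excitation = c(1, 0.3 + 0.2i))
  p <- radial_power_flux(sol, c(2, 8, 14.9, 16, 20, 24.9, 26, 40, 80))
  # all-lossless: net flux through every cylinder is the same (zero) within
  # 1e-6 of the local power magnitude scale
  expect_lt(max(abs(p$flux - p$flux[1])) / max(p$scale), 1e-6)
  expect_lt(max(abs(p$flux)) / max(p$scale), 1e-6)
})

test_that("arm stack solves cleanly and fields behave physically", {
  st <- arm_stack(arm_phantom(), f0)
  for (n in c(0L, 1L, 4L)) {
    sol <- solve_amplitudes(st, mode_spec(n = n, kz = 0, freq = f0))
    expect_lt(attr(sol, "residual"), 1e-8)
    # core field finite at r = 0; zero there for n >= 1
    fr <- axial_fields(sol, c(0, 7.5, 15))
    expect_true(all(is.finite(Re(fr$E_ax))))
    if (n >= 1) expect_identical(fr$E_ax[1], 0 + 0i)
    if (n == 0) expect_equal(fr$E_ax[1], sol$A_E[1], tolerance = 1e-12)
  }
  # tangential E continuity across each interface (inner vs outer side)
  sol <- solve_amplitudes(st, mode_spec(n = 0, kz = 0, freq = f0))
  for (a in c(15, 19, 25, 27)) {
    inner <- axial_fields(sol, a)$E_ax
    outer <- axial_fields(sol, a + 1e-9)$E_ax
    expect_equal(inner, outer, tolerance = 1e-7)
  }
  # the scattered outgoing wave obeys the asymptotic Hankel 1/sqrt(r) decay
  k_air <- 2 * pi * f0 / 299792458
  L <- nrow(sol)
  out_mag <- vapply(c(40, 80, 160) / 1000, function(r_m)
    Mod(sol$B_E[L] * bonewave:::bw_H1(0L, k_air * r_m + 0i)), numeric(1))
  expect_true(all(diff(out_mag) < 0))
  expect_equal(out_mag[2] / out_mag[1], sqrt(1 / 2), tolerance = 0.02)
})

test_that("plane-wave synthesis converges at the default truncation", {
  st <- arm_stack(arm_phantom(), f0)
  expect_gte(n_max_default(st, f0), 10)
  pw <- solve_plane_wave(st, f0)
  expect_true(all(pw$converged))
  expect_lt(max(pw$residual), 1e-8)
  # scattered harmonics decay with order
  expect_lt(Mod(pw$B_E[nrow(pw)]), 1e-6 * max(Mod(pw$B_E)))
})

test_that("stack validation rejects degenerate geometries", {
  expect_error(cyl_stack(cyl_layer(10, 4)), "at least")
  expect_error(cyl_stack(cyl_layer(10, 4), cyl_layer(10, 2),
                         cyl_layer(Inf, 1)), "strictly increasing")
  expect_error(cyl_stack(cyl_layer(10, 4), cyl_layer(20, 2)), "unbounded")
})
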