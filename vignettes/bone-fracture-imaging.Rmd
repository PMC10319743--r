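---
title: "Microwave bone-fracture imaging: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave bone-fracture imaging: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonewave)
```

## The problem

Bone fractures are conventionally imaged with X-ray or CT, whose ionizing dose
limits how often healing can be monitored. At 2.45 GHz the dielectric contrast
between blood (ε′ ≈ 58, σ ≈ 2.5 S/m) and cortical bone (ε′ ≈ 11.4,
σ ≈ 0.39 S/m) is large, so a blood-filled crack perturbs a microwave signal
transmitted through the limb. `bonewave` implements the desk-scale
computational chain behind a dual-polarized transceiver that exploits this: a
pair of patch sensors facing each other across the arm, raster-scanned
longitudinally and rotationally, recording the two-port transmission
coefficient S21 at each position. Images are built from the *phase difference*
of S21 between a fractured limb and a healthy reference, and the crack's
orientation is read off by comparing the two orthogonal polarizations.

The package has four computational layers, each usable on its own:

1. **Tissue electromagnetics** (`tissue_registry()`, `propagation_constants()`,
   `cascade_power_budget()`, `snell_refraction()`): plane-wave propagation in
   lossy tissue and layered power budgets.
2. **Sensor design calculators** (`reflection_phase()`,
   `required_reactance()`, `dda_effective_permittivity()`,
   `quarter_wave_thickness()`): closed forms for the reactive impedance
   surface under the patch and the via-loaded matching lens above it.
3. **Cylindrical mode matching** (`cyl_stack()`, `solve_amplitudes()`,
   `axial_fields()`): near-field wave solutions in the concentric
   air–skin–fat–muscle–bone model of the arm.
4. **Raster-scan forward model and imaging** (`raster_scan()`,
   `phase_image()`, `classify_crack()`): a ray surrogate for the full-wave
   scan, phase-difference image construction, and orientation classification.

## Tissue propagation model

Each tissue is a conductive dielectric with relative permittivity ε′ and
conductivity σ. Under the $e^{+j\omega t}$ phasor convention the complex
relative permittivity is $\varepsilon' - j\,\sigma/(\omega\varepsilon_0)$ and
a plane wave decays as $e^{-\gamma z}$, $\gamma = \alpha + j\beta$ with

$$\alpha = \omega\sqrt{\frac{\mu\varepsilon}{2}\Big[\sqrt{1 +
(\sigma/\omega\varepsilon)^2} - 1\Big]},\qquad
\beta = \omega\sqrt{\frac{\mu\varepsilon}{2}\Big[\sqrt{1 +
(\sigma/\omega\varepsilon)^2} + 1\Big]}.$$

The built-in registry carries the commonly tabulated arm-tissue values at
2.45 GHz (skin ε′ = 38, σ = 1.462; fat 5.28, 0.116; muscle 52.7, 1.744; bone
11.4, 0.39; blood 58.2, 2.54; one-way thicknesses 2/6/4/15 mm). Two numerical
conventions deserve note:

* **σ is authoritative.** Tabulated loss factors ε″ and conductivities are
  mutually inconsistent at a single frequency (both are rounded measurement
  summaries); all propagation computations derive loss from σ, and
  `eps_imag_discrepancy()` reports the disagreement instead of hiding it. The
  same tables print attenuation coefficients (e.g. fat 8.52 Np/m) that differ
  from direct evaluation of the expressions above by up to ~11%; the package
  computes α from the expressions (fat 9.48 Np/m) and keeps the printed
  values as reference metadata (`alpha_ref`), because the tabulated per-layer
  dB values themselves agree with the *computed* α (skin: 44.24 Np/m over a
  doubled 2 mm layer gives −0.77 dB, matching the table to two decimals).
* **dB convention.** Layer attenuation is reported as
  $10\log_{10} e^{-\alpha L}$, i.e. $e^{-\alpha L}$ read on the power scale.
  This is the convention under which the tabulated −0.77 dB skin figure is
  reproduced, and it is applied uniformly. Callers who want the amplitude
  convention can double it.
* **Two-pass doubling.** With transmitter and receiver on opposite sides of
  the limb, every annular layer is crossed twice. The doubling lives in path
  construction (`layer_path(double_pass = TRUE)`, `diametric_path()`), never
  inside `layer_attenuation_db()` itself.

The power budget works on the tabulated approximate per-layer loss
percentages (skin 20, fat 10, muscle 30, bone 50, blood 85): cascading
multiplicatively gives 28% cumulative loss after fat, ≈75% through a healthy
bone path, ≈92.5% when blood replaces the bone, hence a ≈17.5-point
received-power contrast between healthy and fully blood-replaced paths. These
are bookkeeping percentages, deliberately coarser than the Eq.-level α values
(the same cascade computed from α gives ≈19 points); the package keeps both
routes and never mixes them silently.

The refraction helper solves Snell's law in permittivity form,
$\sin\theta_t = \sqrt{\varepsilon_1/\varepsilon_2}\,\sin\theta_i$. For the
skin→fat interface at θ\_i = 10° this gives 27.8°; total internal reflection
is signalled as a flag, not an error.

## Sensor design calculators

**Reactive impedance surface.** A textured ground layer of surface impedance
$Z_s$ under the patch reflects a normally incident wave with phase
$\phi = \mathrm{Im}\,[\mathrm{Ln}\,(Z_s-\eta)/(Z_s+\eta)]$. A short behaves
as a PEC (φ = 180°), an open as an AMC (φ → 0°); an inductive surface sits in
between and adds series inductance, shrinking the patch resonator.
`required_reactance()` is the closed-form inverse
$X = \eta\tan((180°-\phi)/2)$: a 145° design phase needs X ≈ 118.8 Ω. No
analytic map from patch geometry to $Z_s$ is attempted — that is a full-wave
problem, and the package deliberately exposes only the φ ↔ X pair.

**Matching lens.** The ideal permittivity of a quarter-wave matching layer
between media a and b is the geometric mean $\sqrt{\varepsilon_a
\varepsilon_b}$ (air→skin: 6.16), with thickness $c/(4f\sqrt\varepsilon)$. A
printable lens host (PLA, ε = 3) is brought closer to that ideal by
sub-wavelength dielectric vias (ε = 5.28, mimicking fat) treated as electric
dipoles, valid while $\pi D/\lambda < 1$ (D = 4 mm at 2.45 GHz: ratio 0.10).
The mixing rule is the Maxwell Garnett / discrete-dipole form

$$\varepsilon_{\mathrm{eff}} = \varepsilon_H + \frac{3F\varepsilon_H\,r}{1 -
F\,r},\qquad r = \frac{\varepsilon_r - \varepsilon_H}{\varepsilon_r +
2\varepsilon_H},$$

which at the design fill F = 0.14 gives 3.26 (quoted as 3.3 at one decimal).
The volume fraction F is an explicit *input*: it is the ratio of via volume
to the portion of the lens actually involved in propagation, which depends on
aperture illumination, so `via_volume_fraction()` takes the effective volume
as a parameter rather than guessing it. (A quoted companion value of 3.94 at
F ≈ 0.32 is not reproducible from this formula — it evaluates to 3.62 — and
is therefore not treated as a reference point.) The dipole criterion defaults
to the free-space wavelength; the in-medium wavelength is available via
`eps_medium`.

## Cylindrical mode matching

The arm is modelled as an infinite concentric cylinder: bone core (region I),
skin/fat/muscle annuli (region II), unbounded air outside (region III). Per
azimuthal harmonic n and axial wavenumber $k_z$, the axial field pair
$(E_{ax}, H_{ax})$ uses Bessel functions $J_n$ in the core (finite on the
axis), $J_n$ plus outgoing Hankel $H^{(1)}_n$ in the annuli, and incident
$J_n$ plus scattered $H^{(1)}_n$ outside. This module uses the
$e^{-i\omega t}$ time convention so that $H^{(1)}_n$ is the outgoing wave and
lossy permittivities carry a *positive* imaginary part — the sign map to the
scalar formulas above is a complex conjugate. Radial wavenumbers
$k_r = \sqrt{\omega^2\mu\varepsilon - k_z^2}$ are taken on the branch
Im k\_r ≥ 0 so outgoing waves decay.

Matching tangential fields at an interface couples the amplitude 2-vectors
through 2×2 matrices with diagonal entries $\propto \pm i\omega
\{\varepsilon,\mu\}\, k_r r\, Z_n'(k_r r)$ and equal off-diagonal entries
$-n k_z Z_n(k_r r)$, scaled by $1/k_r^2$ (`modal_matrix_J()`/`_H()`); the
off-diagonals vanish at n = 0 or $k_z = 0$, decoupling TE and TM.
`interface_matrices()` provides the per-boundary transmission/reflection
matrices in the conventional $\frac{2\omega}{\pi k^2 a}\bar D^{-1}
\mathrm{diag}(\varepsilon, -\mu)$ form. With that verbatim prefactor an
identical-media interface yields $T = (1/a)\,\mathbb{1}$ rather than the
identity — a pure normalization of per-layer amplitude bookkeeping, flagged
here because it interacts with any excitation convention.

Partly for that reason, `solve_amplitudes()` does **not** cascade T/R
matrices. It assembles the global block system of raw continuity conditions
($E_{ax}, H_{ax}, H_\phi, E_\phi$ at every interface; at most 16×16 complex
for the five-region arm) and solves it directly with column equilibration.
At these sizes the dense solve is unconditionally well posed, needs no
normalization convention, and reports a physical diagnostic — the worst
relative boundary mismatch, typically below 1e−12. Degenerate (cutoff) modes
with $k_r \to 0$ and singular boundary systems are flagged, never silently
inverted.

No integer-order Bessel/Hankel functions of *complex* argument exist in base
R or the installed package set, so the package computes them: Miller's
normalised downward recurrence for $J_n$ (stable for every order and
argument), Neumann series for $H^{(1)}_{0,1}$ at |z| ≤ 15 switching to the
large-argument asymptotic expansion beyond (the series loses ~e^{|z|} to
cancellation while the asymptotic error is ~e^{−2|z|} there), and stable
upward recurrence for higher Hankel orders. Accuracy is pinned in the tests
by frozen independent reference values and by the Wronskian identity
$J_n H_n' - J_n' H_n = 2i/(\pi z)$ across regimes.

Three physical oracles validate the solver rather than any single number,
since no printed field values exist to compare against: identical-media
interfaces must be exact no-ops; an absorbing half-space behind a boundary of
radius ≥ 100λ must reproduce the planar Fresnel reflection magnitude within
1% (it agrees to ~3×10⁻⁷); and all-lossless stacks must conserve net radial
power flux (the net flux is zero — a standing-wave steady state — and the
residual is checked against the local |E||H| power scale, staying below
10⁻¹⁵). The two-layer case is additionally checked against an independently
coded scalar continuity solve. Excitation is a unit standing wave in the
exterior per harmonic; `solve_plane_wave()` synthesises a plane wave with
Jacobi–Anger weights $i^n$ up to N = max(10, ⌈ka⌉ + 8) and reports
convergence.

## Raster-scan forward model

The full-wave scan is replaced by a ray surrogate grounded in the same
per-tissue propagation constants:

$$S_{21}(d,\alpha,\mathrm{pol}) = G_0 \prod_i e^{-(\alpha_i + j\beta_i)L_i}$$

over the diametric path (skin 2, fat 6, muscle 4, bone 30, muscle 4, fat 6,
skin 2 mm — 54 mm total), with a crack-weighted length of bone replaced by
blood. The effective replaced length is `width × weight`, where the weight in
[0, 1] is the product of:

* a **Gaussian beam footprint** with FWHM 28 mm (the patch aperture side) in
  both the axial and arc-length directions, evaluated as the maximum of the
  2-D Gaussian over the crack centreline. No aperture kernel is prescribed by
  the physics at desk scale; the Gaussian is the standard surrogate for a
  finite aperture and is what gives the images their spatial spread;
* a **polarization coupling** κ: 1 when the incident E-field is tangential to
  the crack's long axis, a residual κ⊥ = 0.05 when perpendicular (chosen so
  the perpendicular image is visibly uninformative — sub-threshold, <10% of
  the tangential contrast — without being identically zero), and a
  |cos θ|/|sin θ| blend floored at κ⊥ for inclined cracks so both
  polarizations respond.

A transverse crack is modelled as a blood disc spanning the whole bone
cross-section, matching how such a fracture is physically realised in a
layered phantom; its azimuth is therefore not an identifiable parameter, and
localization claims for transverse cracks apply to the axial coordinate only.
The crack's electromagnetic effect is pure length substitution on the ray —
a deliberate simplification; treating the blood layer as a dielectric
waveguide would change magnitudes, not the phase-contrast mechanism the
imaging relies on. `G_0` = 0.5 is a fixed real insertion factor standing in
for lens/antenna losses; it cancels exactly in phase differences and keeps
every simulated record passive (|S21| ≤ 1, enforced even under amplitude
noise). S11 is filled with the air–skin Fresnel reflection so datasets carry
both ports; the imaging chain never uses it.

Scan grids: the simulated preset is 9 longitudinal steps over −70…70 mm × 7
rotational steps over −30°…30° (63 positions); the measurement preset is
5 × 5 over −60…60 mm and −40°…40° (25 positions). Noise, when requested, is
additive Gaussian on amplitude in dB and phase in degrees, independent per
record and reproducible from an integer seed; the noise-free model is fully
deterministic.

## Imaging and classification

`phase_image()` forms pixel-wise `wrap(∠S21_scan − ∠S21_baseline)` on
(−180°, 180°]; the healthy reference acts as self-calibration, cancelling
everything position-independent (including G₀ and common fabrication bias).
Because β(blood) > β(bone), a crack appears as a localized negative phase
blob, linear in the replaced length for narrow cracks:
(β_blood − β_bone) × 1 mm ≈ 12.7° at 2.45 GHz, comfortably above the default
2° detection threshold while the perpendicular polarization stays at ~0.6°.

`classify_crack()` compares the two polarizations' peak contrasts: neither
above threshold → no crack; y only → transverse; x only → longitudinal; both
→ inclined. The location estimate is the argmax pixel of the dominant image.
For extended cracks the peak can sit anywhere along the crack's ridge, so the
argmax localizes a point *on* the crack rather than its midpoint; the
recovery tests measure distance to the crack centreline accordingly.

## What the synthetic generator does and does not capture

The generator emulates: the geometry of the scan, per-tissue attenuation and
phase delay, the polarization selectivity of crack coupling, aperture
blurring, layer-thickness variability across individuals (skin 2→2.5 mm, fat
6→7 mm scenarios), and seeded instrument noise. It does **not** capture
multiple scattering between sensors and tissue interfaces, near-field antenna
coupling, frequency dispersion of tissue parameters (single-frequency
registry; no Cole–Cole model), waveguide effects inside the crack, or the
absolute S-parameter levels a full-wave solver or VNA would give. Passing
tests therefore demonstrate the *mechanism* — phase-difference imaging with
dual-polarization orientation discrimination is self-consistent and robust in
this model class — not quantitative agreement with any measured S-parameter
curve, which is explicitly out of scope.

Problem sizes were chosen so the whole suite runs in seconds on one CPU: the
63-position simulated grid everywhere the narrative needs it, 50 randomized
cracks in the recovery property, harmonics to n ≈ 10 in the plane-wave
synthesis, and a 100λ boundary radius in the planar-limit oracle.

## Known limitations

* The tissue registry is single-frequency; sweeping `freqs` in
  `raster_scan()` reuses the same ε′, σ at every bin (the α, β still vary
  with ω), which is adequate near 2.45 GHz only.
* The ray model ignores refraction at curved interfaces; the Snell helper
  quantifies the deviation angle but the scan path stays diametric.
* κ⊥ and the beam FWHM are surrogate parameters, fixed once from the sensor
  aperture geometry and the "perpendicular images are uninformative"
  behaviour; they are not fitted quantities.
* `interface_matrices()` reproduces the conventional textbook form including
  its 1/a normalization quirk; amplitude solving deliberately bypasses it.
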