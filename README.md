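# bonewave

Forward modelling and design toolkit for **dual-polarized microwave bone
fracture detection** at 2.45 GHz.

X-ray and CT cannot be used for frequent monitoring of fracture healing
because of their ionizing dose. At microwave frequencies the dielectric
contrast between blood (ε′ ≈ 58, σ ≈ 2.5 S/m) and cortical bone (ε′ ≈ 11.4,
σ ≈ 0.39 S/m) makes a blood-filled crack visible to a transmission
measurement: two patch sensors face each other across the arm, raster-scan it
longitudinally (d) and rotationally (α), and record the two-port transmission
coefficient S21 at every position. Images are built from the **phase
difference** Δ∠S21 between the fractured limb and a healthy reference, and
the crack orientation is identified by comparing the two orthogonal
polarizations — the incident E-field only couples strongly to a crack when it
is tangential to the crack's long axis.

`bonewave` is for researchers in biomedical microwave sensing who want the
desk-scale computational chain of such a system:

* **Tissue electromagnetics** — a registry of arm-tissue dielectric
  properties at 2.45 GHz; complex propagation constants
  γ = α + jβ with
  α = ω√(µε/2·[√(1+(σ/ωε)²) − 1]) and the matching β radical;
  per-layer attenuation 10·log₁₀ e^(−αL); multiplicative power budgets;
  Snell refraction with TIR flagging.
* **Sensor design calculators** — reactive-impedance-surface reflection phase
  φ = Im Ln[(Zₛ−η)/(Zₛ+η)] and its closed-form inverse
  X = η·tan((180°−φ)/2); Maxwell-Garnett / discrete-dipole effective-medium
  mixing for the via-loaded matching lens; geometric-mean matching
  permittivity and quarter-wave thickness; the πD/λ < 1 dipole criterion.
* **Cylindrical mode matching** — near-field solutions for the concentric
  air–skin–fat–muscle–bone cylinder per azimuthal harmonic, built on
  complex-argument Bessel/Hankel functions implemented in the package,
  validated against planar Fresnel limits and power conservation.
* **Raster-scan simulator and imaging** — a ray forward model
  S21 = G₀·Π exp(−(αᵢ+jβᵢ)Lᵢ) with polarization- and aperture-weighted
  bone→blood substitution at the crack, phase-difference image construction,
  and crack orientation classification, plus Touchstone/CSV/YAML I/O and a
  command-line interface (`inst/cli/bonewave`).

## Worked example

Scan a phantom arm with a 1 mm transverse crack, image it against the healthy
baseline, and classify the crack:

```r
library(bonewave)

healthy <- arm_phantom()                                   # radii 15/19/25/27 mm
cracked <- arm_phantom(crack = crack_spec(width_mm = 1,
                                          orientation = "transverse"))

baseline <- raster_scan(healthy, scan_grid("sim"))         # 9 x 7 x 2 pol = 126 records
scan     <- raster_scan(cracked, scan_grid("sim"))

img_y <- phase_image(scan, baseline, pol = "y")
img_x <- phase_image(scan, baseline, pol = "x")
img_y
#> <phase_image> 9 x 7 (d x alpha), pol = y | peak |dphi| = 12.71 deg

classify_crack(img_x, img_y, threshold_deg = 2)
#> # A tibble: 1 × 6
#>   orientation d0_mm alpha0_deg contrast_x_deg contrast_y_deg threshold_deg
#>   <chr>       <dbl>      <dbl>          <dbl>          <dbl>         <dbl>
#> 1 transverse      0        -30          0.636           12.7             2
```

The y-polarized (tangential) image shows a 12.7° phase blob at the crack's
axial position d₀ = 0 — the 1 mm of bone replaced by blood adds
(β_blood − β_bone)·1 mm ≈ 12.7° of phase delay — while the perpendicular
x-polarized image stays at 0.64°, about 5% of the tangential contrast and
below the 2° threshold: the signature of a *transverse* crack. (A transverse
crack spans the whole bone cross-section, so its azimuth α₀ is not
identifiable; the reported value is a tie over the α axis.)
`autoplot(img_y)` renders the image with ggplot2.

The propagation layer underneath:

```r
propagation_constants("skin", 2.45e9)
#> # A tibble: 1 × 5
#>   tissue       freq alpha  beta gamma
#>   <chr>       <dbl> <dbl> <dbl> <cpl>
#> 1 skin   2450000000  44.2  320. 44.244+319.6088i

layer_attenuation_db("skin", 4, 2.45e9)   # doubled 2 mm layer
#> [1] -0.7685972

cascade_power_budget(c(skin = .2, fat = .1, muscle = .3, bone = .5))
#> # A tibble: 4 × 4
#>   stage  loss_fraction remaining cumulative_loss
#> 1 skin             0.2     0.8             0.2
#> 2 fat              0.1     0.72            0.28
#> 3 muscle           0.3     0.504           0.496
#> 4 bone             0.5     0.252           0.748
```

A healthy diametric path loses ≈75% of the power; replacing the bone stage
with blood (85% loss) raises that to ≈92.5%, a ≈17.5-point received-power
contrast — the energy argument for why the measurement works at all.

## Documentation

The methods vignette (`vignettes/bone-fracture-imaging.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, the numerical choices (time conventions, Bessel-function
implementation, branch cuts, degenerate-mode handling), what the synthetic
scan generator does and does not emulate, and known limitations.
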