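# Raster-scan forward model, phase-difference imaging, crack classification.

test_that("grid presets produce the stated record counts", {
  expect_identical(nrow(raster_scan(healthy_phantom,
                                    scan_grid("sim", pol = "y"))), 63L)
  expect_identical(nrow(raster_scan(healthy_phantom,
                                    scan_grid("meas", pol = "y"))), 25L)
  # records multiply over polarizations and frequencies
  two_freq <- raster_scan(healthy_phantom, scan_grid("meas"),
                          freqs = c(2.3e9, 2.45e9))
  expect_identical(nrow(two_freq), 25L * 2L * 2L)
  expect_error(scan_grid(d_mm = c(0, -1), alpha_deg = 0),
               "strictly increasing")
})

test_that("diametric path crosses every annulus twice plus the bone diameter", {
  p <- diametric_path(healthy_phantom)
  expect_identical(p$tissue,
                   c("skin", "fat", "muscle", "bone", "muscle", "fat", "skin"))
  expect_equal(p$length_mm, c(2, 6, 4, 30, 4, 6, 2))
  expect_equal(sum(p$length_mm), 54)  # full diameter = 2 * r_skin
  thick <- arm_phantom(skin_mm = 2.5)
  expect_equal(sum(diametric_path(thick)$length_mm), 55)
  expect_error(arm_phantom(muscle_mm = 0), "degenerate|> 0")
})

test_that("crack interaction weight honours polarization and geometry", {
  tr <- crack_spec(orientation = "transverse")
  # tangential (y) on-crack: maximal; perpendicular (x): residual coupling
  wy <- crack_interaction_weight(tr, 0, 0, "y")
  wx <- crack_interaction_weight(tr, 0, 0, "x")
  expect_equal(wy, 1)
  expect_lte(wx, 0.05)
  # far from the crack the weight vanishes for both
  expect_lt(crack_interaction_weight(tr, 200, 0, "y"), 1e-8)
  lg <- crack_spec(orientation = "longitudinal")
  expect_equal(crack_interaction_weight(lg, 0, 0, "x"), 1)
  expect_lte(crack_interaction_weight(lg, 0, 0, "y"), 0.05)
  # inclined 45 degrees: both polarizations respond within 2x of each other
  inc <- crack_spec(orientation = "inclined", angle_deg = 45)
  wyi <- crack_interaction_weight(inc, 0, 0, "y")
  wxi <- crack_interaction_weight(inc, 0, 0, "x")
  expect_lt(max(wyi, wxi) / min(wyi, wxi), 2)
  expect_true(all(c(wy, wx, wyi, wxi) >= 0 & c(wy, wx, wyi, wxi) <= 1))
})

test_that("simulate_s21 baseline is position-independent and passive", {
  s_a <- simulate_s21(healthy_phantom, -70, -30, "y")
  s_b <- simulate_s21(healthy_phantom, 35, 10, "y")
  expect_equal(s_a, s_b, tolerance = 1e-14)
  expect_lt(Mod(s_a), 1)
  # crack adds phase delay: fractured phase lags the healthy phase
  ph <- arm_phantom(crack = crack_spec())
  s_f <- simulate_s21(ph, 0, 0, "y")
  dphi <- Arg(s_f) - Arg(s_a)
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(dphi, 0)
  # analytic magnitude drop for full bone -> blood replacement:
  # |S21_f| / |S21_h| = exp(-(alpha_blood - alpha_bone) * L_bone)
  full <- arm_phantom(crack = crack_spec(width_mm = 30, extent_mm = 400,
                                         orientation = "transverse"))
  s_full <- simulate_s21(full, 0, 0, "y")
  da <- propagation_constants("blood", 2.45e9)$alpha -
    propagation_constants("bone", 2.45e9)$alpha
  expect_equal(Mod(s_full) / Mod(s_a), exp(-da * 0.030), tolerance = 1e-10)
})

test_that("raster_scan records equal the per-position reference model", {
  ph <- arm_phantom(crack = crack_spec(orientation = "inclined",
                                      angle_deg = 40, center_d_mm = 10))
  ds <- raster_scan(ph, scan_grid(d_mm = c(-20, 0, 15), alpha_deg = c(-10, 5)))
  ref <- purrr::map_vec(seq_len(nrow(ds)), function(i)
    simulate_s21(ph, ds$d_mm[i], ds$alpha_deg[i], ds$pol[i], ds$freq_hz[i]))
  expect_equal(ds$s21, ref, tolerance = 1e-12)
})

test_that("scans are passive, deterministic given a seed, and noise-free stable", {
  ph <- arm_phantom(crack = crack_spec())
  noisy1 <- raster_scan(ph, scan_grid("meas"), noise_sd_amp_db = 0.5,
                        noise_sd_phase_deg = 2, seed = 99L)
  noisy2 <- raster_scan(ph, scan_grid("meas"), noise_sd_amp_db = 0.5,
                        noise_sd_phase_deg = 2, seed = 99L)
  expect_identical(noisy1$s21, noisy2$s21)
  other <- raster_scan(ph, scan_grid("meas"), noise_sd_amp_db = 0.5,
                       noise_sd_phase_deg = 2, seed = 100L)
  expect_false(identical(noisy1$s21, other$s21))
  expect_true(all(Mod(noisy1$s21) <= 1))
  expect_true(all(Mod(noisy1$s11) <= 1))
  # noise-free scans carry no RNG dependence at all
  clean1 <- raster_scan(ph, scan_grid("meas"))
  clean2 <- raster_scan(ph, scan_grid("meas"), seed = 5L)
  expect_identical(clean1$s21, clean2$s21)
})

test_that("frequency sampling picks the nearest stored bin", {
  ds <- raster_scan(healthy_phantom, scan_grid("meas", pol = "y"),
                    freqs = c(2.3e9, 2.45e9, 2.6e9))
  exact <- sample_at_frequency(ds, 2.45e9)
  expect_identical(attr(exact, "selected_freq"), 2.45e9)
  expect_identical(nrow(exact), 25L)
  expect_warning(near <- sample_at_frequency(ds, 2.44e9), "nearest")
  expect_identical(attr(near, "selected_freq"), 2.45e9)
  single <- raster_scan(healthy_phantom, scan_grid("meas", pol = "y"))
  expect_identical(sample_at_frequency(single, 2.45e9)$s21, single$s21)
  expect_error(sample_at_frequency(single[0, ], 2.45e9), "Empty")
})

test_that("healthy-vs-healthy phase image is identically zero", {
  img <- phase_image(baseline_scan_sim, baseline_scan_sim, pol = "y")
  expect_identical(max(abs(img$phase_deg)), 0)
  expect_identical(dim(img$phase_deg), c(9L, 7L))
  # tidy() returns the long form with matching pixel count
  td <- tidy(img)
  expect_identical(nrow(td), 63L)
  expect_identical(max(abs(td$phase_diff_deg)), 0)
})

test_that("grid mismatch between scan and baseline is an error", {
  other <- raster_scan(healthy_phantom, scan_grid("meas"))
  expect_error(phase_image(baseline_scan_sim, other, pol = "y"),
               "do not match")
})

test_that("transverse crack: tangential blob, perpendicular near-silence", {
  sc <- scan_with_crack(crack_spec(orientation = "transverse"))
  iy <- phase_image(sc, baseline_scan_sim, pol = "y")
  ix <- phase_image(sc, baseline_scan_sim, pol = "x")
  # blob centred at the crack's axial position
  peak <- which(abs(iy$phase_deg) == max(abs(iy$phase_deg)), arr.ind = TRUE)
  expect_lte(abs(iy$d_mm[peak[1, 1]] - 0), grid_step(iy$d_mm))
  # above-half-peak pixels form one contiguous d-band (single connected blob)
  hot_rows <- which(apply(abs(iy$phase_deg), 1,
                          max) > 0.5 * max(abs(iy$phase_deg)))
  expect_true(all(diff(hot_rows) == 1))
  # perpendicular image peak < 10% of tangential peak
  expect_lt(max(abs(ix$phase_deg)), 0.10 * max(abs(iy$phase_deg)))
})

test_that("orientation classification matches the crack type", {
  cl_t <- classify_case(crack_spec(orientation = "transverse"))
  expect_identical(cl_t$orientation, "transverse")
  cl_l <- classify_case(crack_spec(orientation = "longitudinal"))
  expect_identical(cl_l$orientation, "longitudinal")
  cl_i <- classify_case(crack_spec(orientation = "inclined", angle_deg = 45))
  expect_identical(cl_i$orientation, "inclined")
  cl_none <- classify_crack(
    phase_image(baseline_scan_sim, baseline_scan_sim, "x"),
    phase_image(baseline_scan_sim, baseline_scan_sim, "y"))
  expect_identical(cl_none$orientation, "none")
  expect_true(is.na(cl_none$d0_mm))
  # glance returns the plain one-row record
  expect_identical(glance(cl_t)$orientation, "transverse")
})

test_that("random cracks are recovered and localized across 50 seeded cases", {
  set.seed(2026)
  grid <- scan_grid("sim")
  d_step <- grid_step(grid$d_mm)        # 17.5 mm
  a_step <- grid_step(grid$alpha_deg)   # 10 deg
  n_cases <- 50L
  oris <- sample(c("transverse", "longitudinal", "inclined"), n_cases,
                 replace = TRUE)
  d0s <- runif(n_cases, -40, 40)
  a0s <- runif(n_cases, -20, 20)
  angs <- runif(n_cases, 30, 60)
  ok_orient <- ok_loc <- logical(n_cases)
  r_surf <- healthy_phantom$radii_mm[["skin"]]
  for (i in seq_len(n_cases)) {
    cr <- crack_spec(orientation = oris[i], angle_deg = angs[i],
                     center_d_mm = d0s[i], center_alpha_deg = a0s[i])
    cl <- classify_case(cr)
    ok_orient[i] <- cl$orientation == oris[i]
    # localization: the peak pixel lies within one grid step of the crack —
    # its centreline for extended (longitudinal/inclined) cracks, whose peak
    # response sits anywhere along the ridge, not at the segment midpoint; a
    # transverse crack spans the full cross-section so only d is identifiable
    th <- cr$angle_deg * pi / 180
    tt <- seq(-cr$extent_mm / 2, cr$extent_mm / 2, length.out = 101)
    line_d <- d0s[i] + tt * sin(th)
    line_a <- a0s[i] + tt * cos(th) / (r_surf * pi / 180)
    near <- if (oris[i] == "transverse") {
      abs(cl$d0_mm - d0s[i]) <= d_step
    } else {
      any(abs(cl$d0_mm - line_d) <= d_step &
            abs(cl$alpha0_deg - line_a) <= a_step)
    }
    ok_loc[i] <- !is.na(cl$d0_mm) && near
  }
  expect_gte(mean(ok_orient), 0.95)
  expect_gte(mean(ok_loc), 0.95)
})

test_that("peak contrast is non-decreasing in crack width", {
  peaks <- vapply(c(1, 2, 4), function(w) {
    sc <- scan_with_crack(crack_spec(width_mm = w))
    max(abs(phase_image(sc, baseline_scan_sim, "y")$phase_deg))
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("detection persists when skin or fat thickens", {
  for (args in list(list(skin_mm = 2.5), list(fat_mm = 7))) {
    healthy_thick <- do.call(arm_phantom, args)
    base <- raster_scan(healthy_thick, scan_grid("sim"))
    sc <- scan_with_crack(crack_spec(), phantom_args = args)
    cl <- classify_crack(phase_image(sc, base, "x"),
                         phase_image(sc, base, "y"))
    expect_identical(cl$orientation, "transverse")
    expect_gt(cl$contrast_y_deg, cl$threshold_deg)
    # the thicker layer changes the healthy baseline itself
    expect_false(isTRUE(all.equal(
      Arg(base$s21[1]), Arg(baseline_scan_sim$s21[1]))))
  }
})
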