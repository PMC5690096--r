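test_that("zero distortion model produces identical volumes and zero truth", {
  pair <- small_pair()
  expect_identical(pair$reference$data, pair$distorted$data)
  expect_true(all(pair$truth$d_mag == 0))
  expect_false(any(pair$truth$ambiguous))
})

test_that("radial cubic model evaluates to its closed form at the markers", {
  model <- radial_cubic_model(magnitude_mm = 2, at_radius_mm = 150)
  # |d| = 2 mm at any point 150 mm from the isocenter, radially outward
  p <- cbind(150 / sqrt(3), 150 / sqrt(3), 150 / sqrt(3))
  d <- evaluate_distortion(model, p)
  expect_equal(sqrt(sum(d^2)), 2, tolerance = 1e-12)
  expect_equal(d / sqrt(sum(d^2)), p / 150, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero at the isocenter, also for polynomial terms
  poly <- tibble::tibble(axis = 2L, px = 1L, py = 0L, pz = 1L, coef = 1e-4)
  m2 <- distortion_model(radial_a = 1e-7, poly = poly)
  expect_equal(evaluate_distortion(m2, cbind(0, 0, 0)),
               matrix(0, 1, 3))
  expect_equal(evaluate_distortion(m2, cbind(10, 5, 20))[, 2],
               1e-7 * (10^2 + 5^2 + 20^2) * 5 + 1e-4 * 10 * 20)
  # degree bounds enforced
  expect_error(distortion_model(poly = tibble::tibble(
    axis = 1L, px = 6L, py = 0L, pz = 0L, coef = 1)), "degree")
})

test_that("default lattice yields about 2500 markers inside the scanner FOV", {
  pts <- lattice_points(lattice_spec())
  expect_gt(nrow(pts), 2250)
  expect_lt(nrow(pts), 2750)
  # 16 x 16 in-plane positions, 15 z planes including the isocenter plane
  expect_length(unique(pts$x), 16)
  expect_length(unique(pts$z), 15)
  expect_true(any(pts$z == 0))
})

test_that("overlarge displacements are flagged as ambiguous with a warning", {
  big <- distortion_model(radial_a = 20 / 75^3)  # 20 mm at r = 75
  expect_warning(pair <- small_pair(big), "ambiguous")
  expect_true(any(pair$truth$ambiguous))
  r <- sqrt(pair$truth$x^2 + pair$truth$y^2 + pair$truth$z^2)
  expect_equal(pair$truth$ambiguous, pair$truth$d_mag > 12.5)
})

test_that("grid phantom generation is reproducible under a seed", {
  a <- small_pair(noise_sd = 0.05, seed = 7)
  b <- small_pair(noise_sd = 0.05, seed = 7)
  expect_identical(a$reference$data, b$reference$data)
  expect_identical(a$distorted$data, b$distorted$data)
})

test_that("phase pair generator matches its closed form and wraps correctly", {
  # uniform zero field: both phases constant at the receiver offset
  pp0 <- gen_phase_pair(function(xyz) rep(0, nrow(xyz)), phi0 = 0.3,
                        spacing = c(7, 7, 10))
  m <- pp0$phase1$meta$mask
  expect_equal(unique(pp0$phase1$data[m]), 0.3)
  expect_equal(unique(pp0$phase2$data[m]), 0.3)
  expect_true(all(pp0$truth$data == 0))

  # parabolic peak 2 ppm: wrapped phase at the peak voxel matches arithmetic
  f0 <- 42587276
  pp <- gen_phase_pair(ppm_parabolic(2, 155), te1_ms = 10, te2_ms = 12,
                       f0_hz = f0, phi0 = 0, spacing = c(5, 5, 5))
  co <- vol_coords(pp$phase1)
  r <- sqrt(rowSums(co^2))
  # voxel closest to the sphere surface along +x
  vi <- which.min(abs(co[, 1] - 155) + abs(co[, 2]) + abs(co[, 3]))
  ppm_here <- 2 * r[vi]^2 / 155^2
  expect_equal(pp$phase1$data[vi],
               wrap_phase(2 * pi * f0 * ppm_here * 1e-6 * 10e-3),
               tolerance = 1e-9)
  dphi_peak <- 2 * pi * f0 * 2e-6 * 0.002  # 2 ppm over dTE = 2 ms
  expect_equal(wrap_phase(pp$phase2$data[vi] - pp$phase1$data[vi]),
               wrap_phase(dphi_peak * r[vi]^2 / 155^2), tolerance = 1e-9)

  # determinism and the Itoh guard
  a <- gen_phase_pair(ppm_parabolic(2, 155), noise_sd = 0.1, seed = 3,
                      spacing = c(7, 7, 10))
  b <- gen_phase_pair(ppm_parabolic(2, 155), noise_sd = 0.1, seed = 3,
                      spacing = c(7, 7, 10))
  expect_identical(a$phase1$data, b$phase1$data)
  expect_error(gen_phase_pair(ppm_parabolic(4000, 155), spacing = c(7, 7, 10)),
               "Itoh")
})

test_that("ramp volume geometry follows the trigonometric identity", {
  r <- gen_ramp_volume(5, 11)
  expect_equal(r$true_profile_fwhm_mm, 5 / tan(11 * pi / 180))
  expect_equal(r$true_profile_fwhm_mm, 25.72, tolerance = 1e-3)
  expect_equal(gen_ramp_volume(3, 44.9999)$true_profile_fwhm_mm, 3,
               tolerance = 1e-4)
  expect_equal(gen_ramp_volume(1, 11)$true_profile_fwhm_mm,
               1 / tan(11 * pi / 180))
  expect_error(gen_ramp_volume(40, 11), "wider")
  expect_error(gen_ramp_volume(5, 50), "ramp_angle")
})

test_that("multi-echo phantom signal model matches closed forms", {
  spec <- tissue_phantom_spec()
  es <- gen_multiecho_phantom(spec)
  lab <- es$truth$labels
  props <- spec$properties
  # pure water voxel at ultrashort TE: magnitude ~ rho, phase 0
  wsel <- lab == 2
  expect_equal(mean(es$magnitude[[1]]$data[wsel]),
               1 * exp(-0.144 / 40), tolerance = 1e-12)
  expect_equal(unique(es$phase[[1]]$data[wsel]), 0)
  # bone-to-water magnitude ratio at the first Dixon echo: closed form
  bsel <- lab == 4
  ratio <- mean(es$magnitude[[2]]$data[bsel]) / mean(es$magnitude[[2]]$data[wsel])
  expect_equal(ratio, (0.55 * exp(-2.44 / 0.4)) / (1 * exp(-2.44 / 40)),
               tolerance = 1e-10)
  # fat voxel at the out-of-phase TE: phase pi relative to water
  te_op <- 1e3 / (2 * es$dfw_hz)  # 2*pi*dfw*TE = pi
  es2 <- gen_multiecho_phantom(spec, tes_ms = c(0.1, te_op, 2 * te_op))
  fsel <- lab == 3
  expect_equal(unique(abs(es2$phase[[2]]$data[fsel])), pi, tolerance = 1e-9)
  expect_error(gen_multiecho_phantom(spec, tes_ms = c(2, 1, 3)), "ascending")
})

test_that("waveform generator honours period, amplitude and sampling rules", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
  # exactly 10 full cycles: value and slope at start and end agree
  expect_equal(max(w$amplitude) - min(w$amplitude), 2, tolerance = 1e-6)
  zc3 <- sum(diff(sign(w$amplitude)) != 0)
  w5 <- gen_waveform(5, peak_to_peak = 2, duration_s = 30)
  zc5 <- sum(diff(sign(w5$amplitude)) != 0)
  expect_equal(zc3 / zc5, 5 / 3, tolerance = 0.1)
  expect_error(gen_waveform(3, duration_s = 30, dt_s = 0.1), "undersampled")
  expect_error(gen_waveform(3, duration_s = 4), "2 cycles")
  # anomalies are deterministic under a seed
  a1 <- gen_waveform(3, duration_s = 30, seed = 5,
                     anomaly = list(type = "irregular", jitter_sd_s = 0.2))
  a2 <- gen_waveform(3, duration_s = 30, seed = 5,
                     anomaly = list(type = "irregular", jitter_sd_s = 0.2))
  expect_identical(a1$amplitude, a2$amplitude)
})

test_that("motion phantom realizes the transmitted excursion and renders the static object", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
  ph <- gen_motion_series(w, excursion_mm = 30, transmission = 0.6)
  expect_equal(ph$realized_excursion_mm, 18)
  # position range over a cycle equals the realized excursion
  amps <- seq(0, 3, by = 0.05)
  zpos <- vapply(amps, function(t) {
    fr <- ph$render_frame(t)
    zc <- vol_axis_coords(fr, 3)
    xin <- vol_axis_coords(fr, 1) < 0
    sum(zc * apply(fr$data[xin, , ], 3, max)) / sum(apply(fr$data[xin, , ], 3, max))
  }, 0)
  expect_equal(max(zpos) - min(zpos), 18, tolerance = 0.5)
  # static object present and fixed in every frame
  f1 <- ph$render_frame(0); f2 <- ph$render_frame(1.3)
  xs <- vol_axis_coords(f1, 1) > 20
  expect_identical(f1$data[xs, , ], f2$data[xs, , ])
  # zero-amplitude waveform: frames identical (static case)
  w0 <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
  w0$amplitude[] <- 0
  ph0 <- gen_motion_series(w0)
  expect_identical(ph0$render_frame(0)$data, ph0$render_frame(7.7)$data)
})
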