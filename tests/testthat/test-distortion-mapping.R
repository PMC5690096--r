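test_that("marker detection recovers undistorted centroids to sub-voxel accuracy", {
  pair <- small_pair()
  det <- detect_markers(pair$reference, lattice = pair$truth)
  expect_equal(nrow(det), nrow(pair$truth))
  m <- match_control_points(pair$truth, det, max_radius_mm = 12)
  expect_lt(max(m$d_mag), 0.1)
  # lattice indices assigned correctly
  expect_setequal(paste(det$i, det$j, det$k),
                  paste(pair$truth$i, pair$truth$j, pair$truth$k))
})

test_that("detection handles empty volumes and deleted markers", {
  empty <- image_volume(array(0, c(20, 20, 20)), spacing = 2)
  expect_equal(nrow(detect_markers(empty)), 0)

  pair <- small_pair()
  vol <- pair$reference
  # erase the marker nearest the corner
  tr <- pair$truth[which.max(tr_r <- pair$truth$x + pair$truth$y + pair$truth$z), ]
  co <- vol_coords(vol)
  near <- sqrt((co[, 1] - tr$x)^2 + (co[, 2] - tr$y)^2 + (co[, 3] - tr$z)^2) < 10
  vol$data[array(near, dim(vol$data))] <- 0
  det <- detect_markers(vol, lattice = pair$truth)
  expect_equal(nrow(det), nrow(pair$truth) - 1)
  expect_false(any(det$i == tr$i & det$j == tr$j & det$k == tr$k))
})

test_that("matching is exact for trivial and constant-shift cases", {
  pts <- lattice_points(small_lattice())
  ref <- tibble::tibble(i = pts$i, j = pts$j, k = pts$k,
                        x = pts$x, y = pts$y, z = pts$z)
  # identical sets: all zero vectors, nothing unmatched
  f <- match_control_points(ref, ref, max_radius_mm = 12)
  expect_true(all(f$d_mag == 0))
  expect_equal(nrow(attr(f, "unmatched")), 0)
  # constant 1 mm shift: every vector equals the shift
  shifted <- dplyr::mutate(ref, x = x + 0.6, y = y - 0.8)
  f2 <- match_control_points(ref, shifted, max_radius_mm = 12)
  expect_equal(unique(round(f2$dx, 12)), 0.6)
  expect_equal(unique(round(f2$dy, 12)), -0.8)
  expect_equal(unique(round(f2$d_mag, 12)), 1)
  # a missing measured point turns up as unmatched
  f3 <- match_control_points(ref, shifted[-1, ], max_radius_mm = 12)
  expect_equal(nrow(attr(f3, "unmatched")), 1)
  expect_equal(nrow(f3) + nrow(attr(f3, "unmatched")), nrow(ref))
})

test_that("detect-match recovers generator truth vectors for a cubic field", {
  model <- radial_cubic_model(2, 150)
  pair <- small_pair(model)
  res <- map_distortion_3d(pair$reference, pair$distorted,
                           lattice = pair$truth, align = FALSE,
                           shell_edges_mm = c(0, 100))
  joined <- dplyr::inner_join(tidy(res$field), pair$truth,
                              by = c("i", "j", "k"), suffix = c("", "_t"))
  err <- sqrt((joined$dx - joined$dx_t)^2 + (joined$dy - joined$dy_t)^2 +
                (joined$dz - joined$dz_t)^2)
  expect_equal(nrow(joined), nrow(pair$truth))
  expect_lt(sqrt(mean(err^2)), 0.15)
})

test_that("radial shell summary reports the binned statistics it claims", {
  mk_field <- function(x, y, z, dmag) {
    n <- length(x)
    structure(tibble::tibble(
      i = seq_len(n), j = seq_len(n), k = seq_len(n), x = x, y = y, z = z,
      x_meas = x + dmag, y_meas = y, z_meas = z,
      dx = dmag, dy = 0, dz = 0, d_mag = abs(dmag)),
      unmatched = tibble::tibble(),
      class = c("displacement_field", class(tibble::tibble())))
  }
  # all-zero field: every populated shell has zero stats
  f0 <- mk_field(c(10, 60, 120, 170), c(0, 0, 0, 0), c(0, 0, 0, 0),
                 rep(0, 4))
  s0 <- radial_distortion_summary(f0)
  expect_equal(s0$mean_mm, rep(0, 4))
  expect_equal(s0$sd_mm, rep(0, 4))
  expect_equal(s0$max_mm, rep(0, 4))
  # single point at r = 75 with 2.5 mm: the 5-10 cm shell fraction in [2,3)
  f1 <- mk_field(75, 0, 0, 2.5)
  s1 <- radial_distortion_summary(f1)
  expect_equal(s1$frac_2_3mm[s1$r_min == 50], 1)
  expect_equal(s1$frac_ge_3mm[s1$r_min == 50], 0)
  # empty shells report NA, not zero
  expect_true(is.na(s1$mean_mm[s1$r_min == 100]))
  expect_equal(s1$n[s1$r_min == 100], 0)
  # population (n) standard deviation, not sample (n-1)
  f2 <- mk_field(c(60, 70), 0, 0, c(1, 3))
  s2 <- radial_distortion_summary(f2)
  expect_equal(s2$sd_mm[s2$r_min == 50], 1)  # population SD of (1, 3)
  expect_error(radial_distortion_summary(f2[0, ]), "empty")
})

test_that("pipeline is equivariant under rigid translation of both volumes", {
  model <- radial_cubic_model(1.5, 150)
  pair <- small_pair(model)
  base <- map_distortion_3d(pair$reference, pair$distorted,
                            lattice = pair$truth, align = FALSE,
                            shell_edges_mm = c(0, 100))
  # shift both volumes by two voxels along x (content roll keeps geometry)
  roll2 <- function(vol) {
    d <- dim(vol$data)
    vol$data <- vol$data[c(d[1] - 1, d[1], seq_len(d[1] - 2)), , ]
    vol
  }
  ref2 <- roll2(pair$reference); meas2 <- roll2(pair$distorted)
  p2 <- detect_markers(ref2); m2 <- detect_markers(meas2)
  f2 <- match_control_points(p2, m2, max_radius_mm = 12)
  ord1 <- order(base$field$x, base$field$y, base$field$z)
  ord2 <- order(f2$x, f2$y, f2$z)
  expect_equal(f2$dx[ord2], base$field$dx[ord1], tolerance = 1e-6)
  expect_equal(f2$d_mag[ord2], base$field$d_mag[ord1], tolerance = 1e-6)
})

test_that("rigid pre-alignment removes an imposed rigid offset", {
  pts <- lattice_points(small_lattice())
  ref <- tibble::tibble(i = pts$i, j = pts$j, k = pts$k,
                        x = pts$x, y = pts$y, z = pts$z)
  ang <- 1 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  xyz <- cbind(ref$x, ref$y, ref$z) %*% R
  meas <- dplyr::mutate(ref, x = xyz[, 1] + 3, y = xyz[, 2] - 2, z = xyz[, 3] + 1)
  al <- align_rigid(ref, meas, fit_radius_mm = 80)
  f <- match_control_points(ref, al$measured, max_radius_mm = 12)
  expect_lt(max(f$d_mag), 1e-6)
  expect_lt(al$fit_rms_mm, 1e-6)
})

test_that("shell mean distortion is non-decreasing with radius for cubic fields", {
  for (mag in c(1, 2)) {
    model <- radial_cubic_model(mag, 150)
    pair <- small_pair(model)
    res <- map_distortion_3d(pair$reference, pair$distorted,
                             lattice = pair$truth, align = FALSE,
                             shell_edges_mm = c(0, 30, 60, 90, 130))
    means <- res$summary$mean_mm[res$summary$n > 0]
    expect_true(all(diff(means) >= -1e-9))
  }
})
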