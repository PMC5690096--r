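test_that("phase difference wraps the echo subtraction into [-pi, pi)", {
  mk <- function(val, te) {
    v <- image_volume(array(val, c(4, 4, 2)), spacing = 5)
    v$meta <- list(te_ms = te, mask = array(TRUE, c(4, 4, 2)))
    v
  }
  # identical phases: zero difference
  expect_true(all(phase_difference_map(mk(0.7, 10), mk(0.7, 12))$data == 0))
  # -3 and +3 rad: wrap(6) = 6 - 2*pi
  d <- phase_difference_map(mk(-3, 10), mk(3, 12))
  expect_equal(unique(as.vector(d$data)), 6 - 2 * pi)
  expect_equal(d$meta$dte_ms, 2)
  expect_error(phase_difference_map(mk(0, 12), mk(0, 10)), "te2 > te1")
  v1 <- mk(0, 10)
  v2 <- image_volume(array(0, c(5, 5, 2)), spacing = 5)
  v2$meta <- list(te_ms = 12)
  expect_error(phase_difference_map(v1, v2), "same grid")
})

test_that("quality-guided unwrapping recovers ramps across multiple wrap boundaries", {
  # already-smooth field: returned unchanged up to a constant
  sm <- image_volume(array(0.4, c(8, 8, 2)), spacing = 5)
  sm$meta$mask <- array(TRUE, c(8, 8, 2))
  uw <- unwrap_phase_map(sm)
  expect_equal(diff(range(uw$data - sm$data)), 0, tolerance = 1e-12)

  # linear ramp spanning 8*pi (4 wrap crossings)
  n <- 80
  truth <- array(outer(seq(0, 8 * pi, length.out = n), rep(1, n)), c(n, n, 1))
  wrapped <- image_volume(wrap_phase(truth), spacing = 1)
  wrapped$meta$mask <- array(TRUE, dim(truth))
  uw2 <- unwrap_phase_map(wrapped)
  resid <- uw2$data - truth
  resid <- resid - resid[1, 1, 1]
  expect_lt(max(abs(resid)), 1e-6)
  # the removed constant is a multiple of 2*pi
  k <- (uw2$data - truth)[1, 1, 1] / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("noisy smooth fields unwrap without residual 2*pi jumps", {
  set.seed(42)
  n <- 60
  truth <- array(outer(seq(0, 6 * pi, length.out = n), rep(1, n)), c(n, n, 1)) +
    array(stats::rnorm(n * n, 0, 0.1), c(n, n, 1))
  wrapped <- image_volume(wrap_phase(truth), spacing = 1)
  wrapped$meta$mask <- array(TRUE, dim(truth))
  uw <- unwrap_phase_map(wrapped)
  resid <- uw$data - truth
  # all adjacent residual differences well below pi: no leftover jumps
  expect_lt(max(abs(diff(resid[, 1, 1]))), pi / 2)
  expect_lt(max(abs(resid - mean(resid))), pi)
})

test_that("disconnected mask components are unwrapped independently with a flag", {
  n <- 30
  mask <- array(FALSE, c(n, n, 1))
  mask[2:10, 2:28, 1] <- TRUE
  mask[20:28, 2:28, 1] <- TRUE
  truth <- array(outer(seq(0, 4 * pi, length.out = n), rep(1, n)), c(n, n, 1))
  wrapped <- image_volume(wrap_phase(truth), spacing = 1)
  wrapped$meta$mask <- mask
  expect_warning(uw <- unwrap_phase_map(wrapped), "disconnected")
  expect_equal(max(uw$meta$component), 2)
})

test_that("ppm conversion references the masked mean and matches arithmetic", {
  f0 <- 42587276
  mk <- function(vals) {
    v <- image_volume(array(vals, c(4, 4, 1)), spacing = 5)
    v$meta <- list(dte_ms = 2, mask = array(TRUE, c(4, 4, 1)))
    v
  }
  # constant map: zero everywhere (deviation convention)
  expect_true(all(phase_to_ppm(mk(1.3), f0)$data == 0))
  # a voxel 0.535 rad above another maps to ~1 ppm apart at dTE = 2 ms
  vals <- rep(0, 16); vals[1] <- 0.535
  out <- phase_to_ppm(mk(vals), f0)
  excess <- out$data[1] - out$data[2]
  expect_equal(excess, 0.535 / (2 * pi * f0 * 0.002) * 1e6, tolerance = 1e-9)
  expect_equal(excess, 1, tolerance = 0.01)
  # the map is mean-free over the mask
  expect_equal(mean(out$data), 0, tolerance = 1e-12)
  bad <- mk(0); bad$meta$dte_ms <- 0
  expect_error(phase_to_ppm(bad, f0), "echo-time difference")
})

test_that("end-to-end pipeline recovers the programmed field to 0.01 ppm", {
  pp <- gen_phase_pair(ppm_parabolic(2, 155), spacing = c(7, 7, 10))
  fm <- b0_field_map(pp$phase1, pp$phase2)
  mask <- pp$truth$meta$mask
  truth_dev <- pp$truth$data - mean(pp$truth$data[mask])
  expect_lt(max(abs(fm$data[mask] - truth_dev[mask])), 0.01)
})

test_that("field map is invariant to 2*pi offsets and global frequency shifts", {
  pp <- gen_phase_pair(ppm_parabolic(1.5, 155), spacing = c(7, 7, 10))
  base <- b0_field_map(pp$phase1, pp$phase2)
  # add 2*pi k to one input: unchanged (wrap invariance)
  p1b <- pp$phase1
  p1b$data <- wrap_phase(p1b$data + 6 * pi)
  alt <- b0_field_map(p1b, pp$phase2)
  expect_equal(alt$data, base$data, tolerance = 1e-9)
  # add a global frequency offset (constant extra phase difference per TE):
  # the deviation map is unchanged
  off_ppm <- 0.4
  p1c <- pp$phase1; p2c <- pp$phase2
  f0 <- 42587276
  p1c$data <- wrap_phase(p1c$data + 2 * pi * f0 * off_ppm * 1e-6 * 10e-3)
  p2c$data <- wrap_phase(p2c$data + 2 * pi * f0 * off_ppm * 1e-6 * 12e-3)
  alt2 <- b0_field_map(p1c, p2c)
  m <- pp$truth$meta$mask
  expect_equal(alt2$data[m], base$data[m], tolerance = 1e-6)
})

test_that("DSV RMS integrates over the centered sphere only", {
  # zero map
  z <- image_volume(array(0, c(20, 20, 20)), spacing = 10)
  z$meta$mask <- array(TRUE, c(20, 20, 20))
  expect_equal(dsv_rms(z, 150), 0)
  # constant 2 ppm: RMS is 2 regardless of diameter
  z$data[] <- 2
  expect_equal(dsv_rms(z, 150), 2)
  # value only outside the sphere does not contribute
  r <- vol_radius(z)
  z$data[] <- 0; z$data[r > 80] <- 100
  expect_equal(dsv_rms(z, 150), 0)
  expect_error(dsv_rms(z, 2), "no masked voxels")
  # slicewise variant pools and reports per-slice values
  z$data[] <- 1
  sw <- dsv_rms(z, 150, slicewise = TRUE)
  expect_equal(sw$vrms_ppm, 1)
  expect_true(all(sw$by_slice$rms_ppm == 1))
})
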