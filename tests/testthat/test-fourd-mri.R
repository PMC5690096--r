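test_that("trigger calibration places bin-center levels with slope tags", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
  s2 <- calibrate_trigger_levels(w, 2)
  expect_equal(s2$level[s2$phase == 0], 0.5, tolerance = 1e-3)
  expect_equal(s2$level[s2$phase == 1], -0.5, tolerance = 1e-3)
  expect_equal(s2$slope, c("falling", "rising"))
  s10 <- calibrate_trigger_levels(w, 10)
  expect_equal(nrow(s10), 10)
  # levels evenly spaced and symmetric about zero
  expect_equal(sort(s10$level), seq(-0.9, 0.9, by = 0.2), tolerance = 1e-3)
  expect_equal(sum(s10$level), 0, tolerance = 1e-3)
  expect_equal(sum(s10$slope == "falling"), 5)
  # phase 0 is end-inhale (highest level), phase 5 end-exhale (lowest)
  expect_equal(which.max(s10$level) - 1, 0)
  expect_equal(which.min(s10$level) - 1, 5)
  expect_equal(s10$label_pct[s10$phase == 5], 50)
  # flat waveform cannot be calibrated
  wf <- w; wf$amplitude[] <- 1
  expect_error(calibrate_trigger_levels(wf, 4), "flat")
  # a calibration-window spike shifts the observed maximum (documented)
  ws <- gen_waveform(3, peak_to_peak = 2, duration_s = 30,
                     anomaly = list(type = "spike", time_s = 0.75, amplitude = 1,
                                    width_s = 0.2))
  ss <- calibrate_trigger_levels(ws, 2)
  expect_gt(attr(ss, "calib_max"), 1.5)
})

test_that("triggered acquisition acquires every slice-phase pair exactly once", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 400)
  ph <- gen_motion_series(w)
  sc <- calibrate_trigger_levels(w, 4)
  acq <- simulate_triggered_acquisition(ph, w, sc, n_slices = 10, tr_ms = 2000)
  tl <- tidy(acq)
  expect_equal(nrow(tl), 40)
  expect_equal(nrow(dplyr::distinct(tl, slice, phase)), 40)
  # events are disjoint in time (no trigger inside another's TR window)
  expect_true(all(diff(tl$time_s[order(tl$time_s)]) >= 2 - 1e-9))
  # acquisition amplitudes sit on the trigger levels
  a <- stats::approx(w$t_s, w$amplitude, tl$time_s)$y
  lv <- sc$level[match(tl$phase, sc$phase)]
  expect_lt(max(abs(a - lv)), 1e-6)
  # waveform exhaustion raises with the partial timeline attached
  wshort <- gen_waveform(3, peak_to_peak = 2, duration_s = 40)
  err <- tryCatch(
    simulate_triggered_acquisition(gen_motion_series(wshort), wshort,
                                   calibrate_trigger_levels(wshort, 4),
                                   n_slices = 10, tr_ms = 2000),
    error = function(e) e)
  expect_s3_class(err, "mrsimqa_incomplete_acquisition")
  expect_gt(nrow(err$timeline), 0)
})

test_that("duty cycle follows its definition and the worked example", {
  expect_equal(duty_cycle(220, 440), 0.5)
  # back-to-back acquisition with no dead time gives 1
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 400)
  tlless <- list(timeline = tibble::tibble(window_s = rep(2, 10)),
                 totals = list(overall_s = 20))
  class(tlless) <- "fourd_acquisition"
  expect_equal(duty_cycle(tlless), 1)
  expect_error(duty_cycle(220, 0), "positive")
})

test_that("faster breathing yields a higher duty cycle at the ten-phase setting", {
  dur <- 1200
  duty <- vapply(c(3, 5), function(T.) {
    w <- gen_waveform(T., peak_to_peak = 2, duration_s = dur)
    ph <- gen_motion_series(w)
    acq <- simulate_triggered_acquisition(ph, w,
                                          calibrate_trigger_levels(w, 10),
                                          tr_ms = 2000)
    duty_cycle(acq)
  }, 0)
  expect_gt(duty[1], duty[2])
})

test_that("MIP is the voxelwise maximum and monotone in the subset", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 300)
  ph <- gen_motion_series(w)
  sc <- calibrate_trigger_levels(w, 4)
  acq <- simulate_triggered_acquisition(ph, w, sc, n_slices = 5, tr_ms = 2000)
  mip_all <- compute_mip(acq)
  mip_one <- compute_mip(acq, subset = 1)
  expect_identical(mip_one$data, acq$phases[[1]]$data)
  expect_true(all(mip_all$data >= mip_one$data))
  mip_two <- compute_mip(acq, subset = c(1, 3))
  expect_true(all(mip_all$data >= mip_two$data))
  expect_error(compute_mip(acq, subset = integer()), "nonempty")
})

test_that("object extent measures a static cube to within a voxel", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
  w$amplitude[] <- 1e-9 * w$amplitude  # effectively static
  ph <- gen_motion_series(w, object_size_mm = 55)
  fr <- ph$render_frame(0)
  ext <- object_extent(fr, axis = 3, roi = ph$moving_roi)
  expect_equal(ext, 55, tolerance = 2 / 55)
  # a high threshold on a (near) binary object gives the same answer
  expect_equal(object_extent(fr, axis = 3, threshold = 0.9,
                             roi = ph$moving_roi), ext, tolerance = 2 / 55)
  blank <- image_volume(array(0, c(5, 5, 5)), spacing = 2)
  blank$data[3, 3, 3] <- 1
  expect_error(object_extent(blank, axis = 3, threshold = 2), "above threshold")
})

test_that("phase-count study reproduces the captured-excursion and time scaling laws", {
  w <- gen_waveform(3, peak_to_peak = 2, duration_s = 2000)
  ph <- gen_motion_series(w)  # 55 mm cube, realized 18 mm excursion
  st <- phase_count_study(ph, w, phase_counts = c(2, 4, 10), tr_ms = 2000)
  # overall time grows monotonically with the number of phases
  expect_true(all(diff(st$overall_s) > 0))
  # ten-vs-two phase acquisition time ratio in the expected band
  expect_gt(st$overall_s[3] / st$overall_s[1], 3.5)
  expect_lt(st$overall_s[3] / st$overall_s[1], 5.5)
  # MIP S-I extent non-decreasing in N and within one voxel of
  # size + excursion * (N-1)/N
  expect_true(all(diff(st$mip_extent_mm) >= 0))
  law <- 55 + 18 * (st$n_phases - 1) / st$n_phases
  expect_true(all(abs(st$mip_extent_mm - law) <= 2 + 1e-9))
  # identical seeds/waveforms give identical studies
  st2 <- phase_count_study(ph, w, phase_counts = c(2, 4, 10), tr_ms = 2000)
  expect_identical(st$overall_s, st2$overall_s)
  expect_identical(st$mip_extent_mm, st2$mip_extent_mm)
})
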