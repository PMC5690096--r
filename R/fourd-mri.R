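#' Generate a respiratory surrogate waveform
#'
#' Sinusoidal breathing signal `a(t) = (peak_to_peak/2) * sin(2*pi*t/T)`
#' sampled uniformly, with optional anomalies: a linear baseline `drift`, a
#' transient `spike`, or `irregular` cycle-to-cycle period jitter.
#'
#' @param period_s Breathing period T (s).
#' @param peak_to_peak Peak-to-peak amplitude (a.u.).
#' @param duration_s Total duration (s); must cover at least two cycles (the
#'   trigger calibration window).
#' @param dt_s Sampling interval (s); must satisfy `dt_s <= period_s / 50`.
#' @param anomaly Optional list: `list(type = "drift", rate = a.u./s)`,
#'   `list(type = "spike", time_s =, amplitude =, width_s =)`, or
#'   `list(type = "irregular", jitter_sd_s =)`.
#' @param seed Integer seed (used by the irregular anomaly).
#' @return A tibble of class `resp_waveform` with columns `t_s` and
#'   `amplitude`; period, amplitude and sampling parameters are kept as
#'   attributes.
#' @export
gen_waveform <- function(period_s, peak_to_peak = 1, duration_s,
                         dt_s = 0.01, anomaly = NULL, seed = NULL) {
  if (dt_s > period_s / 50) stop("dt_s > period_s / 50: waveform undersampled")
  if (duration_s < 2 * period_s) stop("duration must cover at least 2 cycles")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  if (!is.null(anomaly) && identical(anomaly$type, "irregular")) {
    # phase accumulation with a per-cycle period perturbation
    n_cycles <- ceiling(duration_s / period_s) + 2
    periods <- pmax(stats::rnorm(n_cycles, period_s, anomaly$jitter_sd_s),
                    period_s / 2)
    bounds <- c(0, cumsum(periods))
    cyc <- findInterval(t, bounds)
    phase <- (cyc - 1) + (t - bounds[cyc]) / periods[cyc]
    a <- peak_to_peak / 2 * sin(2 * pi * phase)
  } else {
    a <- peak_to_peak / 2 * sin(2 * pi * t / period_s)
  }
  if (!is.null(anomaly)) {
    if (identical(anomaly$type, "drift")) {
      a <- a + anomaly$rate * t
    } else if (identical(anomaly$type, "spike")) {
      a <- a + anomaly$amplitude *
        exp(-(t - anomaly$time_s)^2 / (2 * anomaly$width_s^2))
    }
  }
  structure(tibble::tibble(t_s = t, amplitude = a),
            period_s = period_s, peak_to_peak = peak_to_peak, dt_s = dt_s,
            anomaly = anomaly,
            class = c("resp_waveform", class(tibble::tibble())))
}

#' Write a waveform to two-column CSV
#' @param waveform A `resp_waveform`.
#' @param path Output path (columns `t_s`, `amplitude`).
#' @export
write_waveform <- function(waveform, path) {
  utils::write.csv(as.data.frame(waveform)[c("t_s", "amplitude")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.resp_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$amplitude)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)")
}

#' Moving-phantom frame sampler for 4D-MRI simulation
#'
#' A cube-shaped signal generator translating in the superior-inferior (z)
#' direction following the respiratory waveform, plus a round static
#' reference object in the same field of view. The realized excursion is the
#' programmed excursion times a mechanical transmission factor, emulating
#' the loss introduced by the string-and-trolley drive of a motion platform
#' (programmed ~3 cm typically realizes ~1.5-2 cm). The object's z position
#' at time t is `realized_excursion * a(t) / peak_to_peak`.
#'
#' @param waveform A `resp_waveform` driving the motion.
#' @param object_size_mm Cube edge length (mm).
#' @param excursion_mm Programmed peak-to-peak excursion (mm).
#' @param transmission Mechanical transmission factor in (0, 1].
#' @param fov_mm Field of view `c(x, y, z)` (mm); y is the slice axis of the
#'   coronal acquisition.
#' @param spacing Voxel size (mm); `spacing[2]` is the slice thickness.
#' @param cube_center_mm Resting cube center (mm).
#' @param static_diameter_mm,static_center_mm Round static reference object
#'   (a cylinder along the slice axis).
#' @return An object of class `motion_phantom`: a list with `render_slice(t,
#'   slice)`, `render_frame(t)`, `n_slices`, `realized_excursion_mm`,
#'   `moving_roi` (a window around the cube for extent measurements) and the
#'   grid geometry.
#' @export
gen_motion_series <- function(waveform, object_size_mm = 55,
                              excursion_mm = 30, transmission = 0.6,
                              fov_mm = c(200, 125, 250),
                              spacing = c(2, 5, 2),
                              cube_center_mm = c(-40, 0, 0),
                              static_diameter_mm = 60,
                              static_center_mm = c(55, 0, 0)) {
  ptp <- attr(waveform, "peak_to_peak")
  realized <- excursion_mm * transmission
  if (abs(cube_center_mm[3]) + object_size_mm / 2 + realized / 2 > fov_mm[3] / 2) {
    stop("object plus excursion does not fit the field of view")
  }
  spacing <- rep_len(spacing, 3L)
  dims <- 2 * floor(fov_mm / 2 / spacing) + 1
  proto <- image_volume(array(0, dims), spacing = spacing)
  xc <- vol_axis_coords(proto, 1)
  yc <- vol_axis_coords(proto, 2)
  zc <- vol_axis_coords(proto, 3)
  aa <- min(spacing[c(1, 3)])
  cover1d <- function(u, center, half) {
    pmin(pmax(0.5 + (half - abs(u - center)) / aa, 0), 1)
  }
  amp <- function(t) {
    stats::approx(waveform$t_s, waveform$amplitude, t, rule = 2)$y
  }
  half <- object_size_mm / 2
  srad <- static_diameter_mm / 2
  rad <- sqrt(outer((xc - static_center_mm[1])^2, (zc - static_center_mm[3])^2, "+"))
  static_xz <- pmin(pmax(0.5 + (srad - rad) / aa, 0), 1)
  render_slice <- function(t, slice) {
    zpos <- cube_center_mm[3] + realized * amp(t) / ptp
    ycov <- cover1d(yc[slice], cube_center_mm[2], half)
    cube <- outer(cover1d(xc, cube_center_mm[1], half),
                  cover1d(zc, zpos, half)) * ycov
    scov <- cover1d(yc[slice], static_center_mm[2], srad)
    pmax(cube, static_xz * scov)
  }
  render_frame <- function(t) {
    arr <- array(0, dims)
    for (s in seq_len(dims[2])) arr[, s, ] <- render_slice(t, s)
    out <- proto
    out$data <- arr
    out$meta <- list(modality = "motion_phantom", time_s = t)
    out
  }
  structure(
    list(waveform = waveform, render_slice = render_slice,
         render_frame = render_frame, n_slices = dims[2],
         dims = dims, spacing = spacing,
         origin = proto$origin,
         realized_excursion_mm = realized,
         object_size_mm = object_size_mm,
         moving_roi = list(xlim = cube_center_mm[1] + c(-1, 1) * (half + 10)),
         static_center_mm = static_center_mm),
    class = "motion_phantom"
  )
}

#' Calibrate amplitude trigger levels from a waveform
#'
#' Analyzes the calibration window (the first two breathing cycles) to find
#' the signal minimum and maximum, then places `n_phases` trigger levels at
#' the centers of equal amplitude bins. Levels are mapped to respiratory
#' phases via slope tags so the inhale and exhale limbs get distinct phases:
#' the falling (exhaling) limb takes every other level from the top and the
#' rising (inhaling) limb the remaining levels from the bottom, which keeps
#' the phase sequence in monotone time order within a cycle. Phase 0
#' (labeled 0%) is end-inhale, phase `n/2` (50%) end-exhale.
#'
#' @param waveform A `resp_waveform`.
#' @param n_phases Number of respiratory phases (>= 2).
#' @return A tibble of class `trigger_scheme` with columns `phase`,
#'   `label_pct`, `level`, `slope`; the calibration window and observed
#'   min/max are stored as attributes.
#' @examples
#' w <- gen_waveform(3, peak_to_peak = 2, duration_s = 30)
#' calibrate_trigger_levels(w, 2)  # levels at -0.5 and +0.5
#' @export
calibrate_trigger_levels <- function(waveform, n_phases) {
  if (n_phases < 2) stop("n_phases must be at least 2")
  period <- attr(waveform, "period_s")
  calib_s <- 2 * period
  if (max(waveform$t_s) < calib_s) stop("waveform shorter than the calibration window")
  win <- waveform$amplitude[waveform$t_s <= calib_s]
  lo <- min(win); hi <- max(win)
  if (hi - lo < .Machine$double.eps^0.5) stop("flat waveform: cannot calibrate trigger levels")
  levels_asc <- lo + (seq_len(n_phases) - 0.5) * (hi - lo) / n_phases
  nf <- ceiling(n_phases / 2)
  p <- 0:(n_phases - 1)
  level <- numeric(n_phases)
  slope <- character(n_phases)
  fall <- p < nf
  level[fall] <- levels_asc[n_phases - 2 * p[fall]]
  slope[fall] <- "falling"
  level[!fall] <- levels_asc[2 * (p[!fall] - nf) + 1]
  slope[!fall] <- "rising"
  structure(
    tibble::tibble(phase = p, label_pct = round(100 * p / n_phases),
                   level = level, slope = slope),
    calib_min = lo, calib_max = hi, calib_s = calib_s,
    class = c("trigger_scheme", class(tibble::tibble()))
  )
}

# linearly interpolated crossing times of one level with given slope
level_crossings <- function(t, a, level, slope) {
  d <- a - level
  n <- length(d)
  s <- d[-n] * d[-1]
  idx <- which(s < 0 | (d[-n] == 0 & d[-1] != 0))
  if (!length(idx)) return(numeric())
  tc <- t[idx] + (t[idx + 1] - t[idx]) * (-d[idx]) / (d[idx + 1] - d[idx])
  rising <- a[idx + 1] > a[idx]
  tc[if (slope == "rising") rising else !rising]
}

#' Simulate an amplitude-triggered 4D-MRI acquisition
#'
#' Scans the waveform forward in time from the end of the calibration
#' window. Each crossing of a still-needed phase's trigger level (with
#' matching slope) triggers acquisition of the next needed slice for that
#' phase; the shot occupies one TR during which no other trigger can fire.
#' Slice data are taken from the moving phantom at the trigger time, so each
#' phase volume assembles slices acquired at (nearly) the same respiratory
#' amplitude across many breathing cycles. Nominal acquisition time is
#' `n_slices * n_phases * TR`; overall scan time runs from the end of
#' calibration to the end of the last shot (calibration excluded from both).
#'
#' @param phantom A `motion_phantom` from [gen_motion_series()].
#' @param waveform The driving `resp_waveform` (defaults to the phantom's).
#' @param scheme A `trigger_scheme` from [calibrate_trigger_levels()].
#' @param n_slices Number of slices (default: all slices of the phantom).
#' @param tr_ms Repetition time per shot (ms).
#' @return An object of class `fourd_acquisition`: a list with `timeline`
#'   (tibble `time_s`, `slice`, `phase`, `window_s`), `totals` (list
#'   `nominal_s`, `overall_s`, `calibration_s`), and `phases` (one
#'   [image_volume()] per respiratory phase).
#' @export
simulate_triggered_acquisition <- function(phantom, waveform = phantom$waveform,
                                           scheme, n_slices = phantom$n_slices,
                                           tr_ms = 2000) {
  tr_s <- tr_ms / 1000
  calib_s <- attr(scheme, "calib_s")
  n_phases <- nrow(scheme)
  ev <- purrr::map_dfr(seq_len(n_phases), function(r) {
    tc <- level_crossings(waveform$t_s, waveform$amplitude,
                          scheme$level[r], scheme$slope[r])
    tibble::tibble(time_s = tc[tc > calib_s], phase = scheme$phase[r])
  })
  ev <- ev[order(ev$time_s), ]
  need <- rep(n_slices, n_phases)
  next_slice <- rep(1L, n_phases)
  t_free <- calib_s
  events <- vector("list", n_slices * n_phases)
  n_ev <- 0L
  for (r in seq_len(nrow(ev))) {
    ph <- ev$phase[r]
    if (ev$time_s[r] >= t_free && need[ph + 1L] > 0L) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- c(time_s = ev$time_s[r], slice = next_slice[ph + 1L],
                          phase = ph)
      need[ph + 1L] <- need[ph + 1L] - 1L
      next_slice[ph + 1L] <- next_slice[ph + 1L] + 1L
      t_free <- ev$time_s[r] + tr_s
      if (all(need == 0L)) break
    }
  }
  if (n_ev > 0L) {
    timeline <- tibble::as_tibble(do.call(rbind, events[seq_len(n_ev)]))
    timeline$slice <- as.integer(timeline$slice)
    timeline$phase <- as.integer(timeline$phase)
  } else {
    timeline <- tibble::tibble(time_s = numeric(), slice = integer(),
                               phase = integer())
  }
  timeline$window_s <- rep(tr_s, nrow(timeline))
  if (any(need > 0L)) {
    abort(sprintf("waveform exhausted with %d slice-phase pairs still unacquired",
                  sum(need)),
          class = "mrsimqa_incomplete_acquisition",
          timeline = timeline)
  }
  proto <- image_volume(array(0, phantom$dims), spacing = phantom$spacing,
                        origin = phantom$origin)
  phases <- purrr::map(0:(n_phases - 1), function(p) {
    vol <- proto
    rows <- timeline[timeline$phase == p, ]
    for (q in seq_len(nrow(rows))) {
      vol$data[, rows$slice[q], ] <- phantom$render_slice(rows$time_s[q],
                                                          rows$slice[q])
    }
    vol$meta <- list(modality = "4dmri_phase", phase = p,
                     label_pct = scheme$label_pct[scheme$phase == p])
    vol
  })
  overall <- max(timeline$time_s) + tr_s - calib_s
  structure(
    list(timeline = timeline,
         totals = list(nominal_s = n_slices * n_phases * tr_s,
                       overall_s = overall, calibration_s = calib_s),
         phases = phases, scheme = scheme, phantom = phantom),
    class = "fourd_acquisition"
  )
}

#' Duty cycle of a triggered acquisition
#'
#' Nominal programmed acquisition time divided by overall scan time
#' (equivalently, the summed acquisition windows over the span of the scan),
#' with the calibration/training period excluded. Can be applied to a
#' simulated `fourd_acquisition` or to raw times, e.g.
#' `duty_cycle(220, 440)` is 0.5.
#'
#' @param x A `fourd_acquisition`, or the nominal acquisition time (s).
#' @param overall_s Overall scan time (s) when `x` is numeric.
#' @return The duty cycle as a fraction in (0, 1].
#' @export
duty_cycle <- function(x, overall_s = NULL) {
  if (inherits(x, "fourd_acquisition")) {
    return(sum(x$timeline$window_s) / x$totals$overall_s)
  }
  if (is.null(overall_s) || overall_s <= 0) stop("overall_s must be positive")
  x / overall_s
}

#' Maximum intensity projection over respiratory phases
#'
#' Voxelwise maximum over a subset of the phase volumes; over all phases it
#' captures the motion envelope of the moving object.
#'
#' @param phases A `fourd_acquisition` or a list of [image_volume()]s on a
#'   common grid.
#' @param subset Phase indices to project (1-based into the list); default
#'   all.
#' @return An [image_volume()].
#' @export
compute_mip <- function(phases, subset = NULL) {
  if (inherits(phases, "fourd_acquisition")) phases <- phases$phases
  subset <- subset %||% seq_along(phases)
  if (!length(subset)) stop("subset must be nonempty")
  vols <- phases[subset]
  for (v in vols[-1]) {
    if (!same_grid(vols[[1]], v)) stop("phase volumes are not on the same grid")
  }
  out <- vols[[1]]
  for (v in vols[-1]) out$data <- pmax(out$data, v$data)
  out$meta <- list(modality = "mip", n_phases = length(vols))
  out
}

#' Object extent along an axis at a threshold
#'
#' Distance between the first and last above-threshold voxel positions along
#' the axis, plus one voxel (edge inclusive), at half-maximum by default.
#' An optional physical ROI restricts the measurement (e.g. to the moving
#' object, excluding the static reference).
#'
#' @param volume An [image_volume()].
#' @param axis Axis index or label (default z).
#' @param threshold Fraction of the maximum intensity.
#' @param roi Optional list with any of `xlim`, `ylim`, `zlim` (mm).
#' @return Extent in mm.
#' @export
object_extent <- function(volume, axis = 3, threshold = 0.5, roi = NULL) {
  if (is.character(axis)) axis <- match(axis, volume$axes)
  data <- volume$data
  if (!is.null(roi)) {
    lims <- list(roi$xlim, roi$ylim, roi$zlim)
    for (ax in 1:3) {
      if (is.null(lims[[ax]])) next
      cc <- vol_axis_coords(volume, ax)
      ix <- lapply(dim(data), seq_len)
      ix[[ax]] <- which(cc >= lims[[ax]][1] & cc <= lims[[ax]][2])
      data <- do.call(`[`, c(list(data), ix, list(drop = FALSE)))
    }
  }
  thr <- threshold * max(volume$data)
  above <- apply(data > thr, axis, any)
  if (!any(above)) stop("no voxels above threshold")
  idx <- range(which(above))
  (idx[2] - idx[1]) * volume$spacing[axis] + volume$spacing[axis]
}

#' Phase-count study: duty cycle and motion envelope versus phase number
#'
#' Runs the full triggered-acquisition chain for each requested phase count
#' on the same waveform and phantom, and reports overall time, duty cycle
#' and the maximum-intensity-projection S-I extent of the moving object
#' (referenced to the largest phase count).
#'
#' @param phantom A `motion_phantom`.
#' @param waveform Driving waveform (defaults to the phantom's).
#' @param phase_counts Increasing vector of phase counts.
#' @param tr_ms Repetition time (ms).
#' @param n_slices Slices per phase (default: all).
#' @return A tibble with one row per phase count: `n_phases`, `nominal_s`,
#'   `overall_s`, `duty_cycle`, `mip_extent_mm`, `extent_pct_vs_max`.
#' @export
phase_count_study <- function(phantom, waveform = phantom$waveform,
                              phase_counts = c(2, 4, 6, 8, 10),
                              tr_ms = 2000, n_slices = phantom$n_slices) {
  if (is.unsorted(phase_counts)) stop("phase_counts must be ascending")
  res <- purrr::map_dfr(phase_counts, function(n) {
    scheme <- calibrate_trigger_levels(waveform, n)
    acq <- simulate_triggered_acquisition(phantom, waveform, scheme,
                                          n_slices = n_slices, tr_ms = tr_ms)
    mip <- compute_mip(acq)
    tibble::tibble(
      n_phases = n,
      nominal_s = acq$totals$nominal_s,
      overall_s = acq$totals$overall_s,
      duty_cycle = duty_cycle(acq),
      mip_extent_mm = object_extent(mip, axis = 3, roi = phantom$moving_roi)
    )
  })
  res$extent_pct_vs_max <- 100 * (res$mip_extent_mm / res$mip_extent_mm[which.max(phase_counts)] - 1)
  res
}

#' @export
tidy.fourd_acquisition <- function(x, ...) x$timeline

#' @export
glance.fourd_acquisition <- function(x, ...) {
  tibble::tibble(
    n_phases = length(x$phases),
    n_slices = max(x$timeline$slice),
    nominal_s = x$totals$nominal_s,
    overall_s = x$totals$overall_s,
    duty_cycle = duty_cycle(x)
  )
}
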