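#' Generate an angled-ramp slice-thickness phantom image
#'
#' The crossed-ramp insert converts slice thickness into an in-plane band
#' width: a ramp inclined at `ramp_angle_deg` to the imaging plane projects a
#' slice of thickness `t` into a band of width `t / tan(angle)`. The
#' generated single-slice volume contains that band (along x, profile along
#' y) with anti-aliased edges; the analytic profile width is returned as
#' ground truth.
#'
#' @param true_thickness_mm Simulated slice thickness (mm).
#' @param ramp_angle_deg Ramp angle in degrees, in (0, 45).
#' @param spacing In-plane voxel size (mm).
#' @param fov_mm In-plane field of view (mm).
#' @return A list with `image` (an [image_volume()], one slice) and
#'   `true_profile_fwhm_mm` (`true_thickness_mm / tan(angle)`).
#' @examples
#' ramp <- gen_ramp_volume(5, 11)
#' ramp$true_profile_fwhm_mm  # ~25.72 mm
#' @export
gen_ramp_volume <- function(true_thickness_mm, ramp_angle_deg = 11,
                            spacing = 1, fov_mm = 180) {
  if (ramp_angle_deg <= 0 || ramp_angle_deg >= 45) {
    stop("ramp_angle_deg must be in (0, 45)")
  }
  width <- true_thickness_mm / tan(ramp_angle_deg * pi / 180)
  if (width >= fov_mm - 4 * spacing) stop("ramp band wider than the image")
  n <- 2 * floor(fov_mm / 2 / spacing) + 1
  vol <- image_volume(array(0, c(n, n, 1)), spacing = c(spacing, spacing, spacing))
  yc <- vol_axis_coords(vol, 2)
  # linear edge over one voxel so the half-maximum crossing sits exactly on
  # the geometric band edge
  cover <- pmin(pmax(0.5 + (width / 2 - abs(yc)) / spacing, 0), 1)
  vol$data <- array(rep(cover, each = n), c(n, n, 1))
  vol$meta <- list(modality = "ramp_phantom", ramp_angle_deg = ramp_angle_deg,
                   true_thickness_mm = true_thickness_mm)
  list(image = vol, true_profile_fwhm_mm = width)
}

# 3-point refinement of a sampled maximum position. The triplet is taken
# `stride` samples apart (one voxel) so that for axis-aligned lines the
# samples are raw voxel values, not interpolated ones; a log-domain parabola
# is exact for Gaussian-shaped peaks, with a plain parabola as fallback for
# non-positive values.
refine_peak <- function(pos, val, imax, stride = 1L) {
  i1 <- imax - stride; i3 <- imax + stride
  if (i1 < 1 || i3 > length(val)) return(pos[imax])
  y <- val[c(i1, imax, i3)]
  if (all(y > 0)) y <- log(y)
  den <- y[1] - 2 * y[2] + y[3]
  if (den >= 0) return(pos[imax])
  delta <- 0.5 * (y[1] - y[3]) / den
  pos[imax] + max(min(delta, 1), -1) * (pos[i3] - pos[imax])
}

#' Peak positions along a line profile
#'
#' Samples the volume along a physical line by trilinear interpolation (at
#' steps no coarser than half a voxel) and locates one intensity peak inside
#' each search box, refined to sub-sample precision by 3-point parabolic
#' interpolation around the maximum sample. Flat boxes yield a missing peak.
#'
#' @param volume An [image_volume()].
#' @param from,to Physical endpoints of the line (length-3, mm).
#' @param boxes List of `c(lo, hi)` intervals of position along the line
#'   (mm from `from`), pairwise disjoint.
#' @param step_mm Sampling step; defaults to half the smallest voxel size.
#' @return A tibble of class `profile_peaks` with one row per box: `box`,
#'   `lo`, `hi`, `peak_pos_mm` (`NA` when no peak was found) and
#'   `peak_value`. The sampled profile is kept in the `profile` attribute.
#' @export
line_profile_peaks <- function(volume, from, to, boxes, step_mm = NULL) {
  step_mm <- step_mm %||% (min(volume$spacing) / 2)
  len <- sqrt(sum((to - from)^2))
  s <- seq(0, len, by = step_mm)
  dirv <- (to - from) / len
  pts <- outer(s, dirv) + matrix(from, length(s), 3, byrow = TRUE)
  prof <- vol_interp(volume, pts)
  if (anyNA(prof)) stop("line leaves the volume")
  los <- vapply(boxes, `[`, 0, 1)
  if (length(boxes) > 1) {
    his <- vapply(boxes, `[`, 0, 2)
    ord <- order(los)
    if (any(los[ord][-1] < his[ord][-length(his)])) stop("search boxes must be disjoint")
  }
  res <- purrr::imap_dfr(boxes, function(b, ib) {
    inb <- which(s >= b[1] & s <= b[2])
    if (!length(inb)) {
      return(tibble::tibble(box = ib, lo = b[1], hi = b[2],
                            peak_pos_mm = NA_real_, peak_value = NA_real_))
    }
    v <- prof[inb]
    if (max(v) - min(v) < 1e-12) {
      return(tibble::tibble(box = ib, lo = b[1], hi = b[2],
                            peak_pos_mm = NA_real_, peak_value = NA_real_))
    }
    im <- which.max(v)
    stride <- max(1L, as.integer(round(min(volume$spacing) / step_mm)))
    tibble::tibble(box = ib, lo = b[1], hi = b[2],
                   peak_pos_mm = refine_peak(s[inb], v, im, stride),
                   peak_value = max(v))
  })
  res <- res[order(res$lo), ]
  structure(res, profile = tibble::tibble(pos_mm = s, intensity = prof),
            class = c("profile_peaks", class(res)))
}

#' Marker-spacing report against a nominal distance
#'
#' Distances between consecutive detected peaks compared with the nominal
#' marker spacing: absolute displacement and percent difference per pair.
#'
#' @param peaks A `profile_peaks` tibble (or any tibble with a
#'   `peak_pos_mm` column); missing peaks are dropped.
#' @param nominal_mm Nominal center-to-center spacing (mm).
#' @return A tibble with one row per consecutive pair: `pair`,
#'   `distance_mm`, `abs_displacement_mm`, `percent_diff`.
#' @export
marker_spacing_report <- function(peaks, nominal_mm = 60) {
  pos <- sort(peaks$peak_pos_mm[!is.na(peaks$peak_pos_mm)])
  if (length(pos) < 2) stop("need at least 2 detected peaks")
  d <- diff(pos)
  tibble::tibble(
    pair = paste(seq_along(d), seq_along(d) + 1, sep = "-"),
    distance_mm = d,
    abs_displacement_mm = abs(d - nominal_mm),
    percent_diff = 100 * (d - nominal_mm) / nominal_mm
  )
}

#' Threshold segmentation of high-intensity structures
#'
#' Thresholds at a fraction of the foreground-background intensity range
#' (half-maximum by default), labels 3-D connected components and keeps the
#' `keep` largest. This replaces operator-windowed treatment-planning-system
#' thresholding with a reproducible rule.
#'
#' @param volume An [image_volume()].
#' @param threshold Fraction of the min-max intensity range, in (0, 1).
#' @param keep Number of largest components to keep (default all).
#' @return An integer label array (same shape as the image): 0 background,
#'   1..keep labels ordered by decreasing voxel count.
#' @export
threshold_segment <- function(volume, threshold = 0.5, keep = Inf) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  rng <- range(volume$data)
  thr <- rng[1] + threshold * (rng[2] - rng[1])
  mask <- volume$data > thr
  if (!any(mask) || rng[1] == rng[2]) {
    return(array(0L, dim(volume$data)))
  }
  lab <- .cc_label3d(mask, dim(volume$data), 26L)
  sizes <- tabulate(lab[lab > 0L])
  ord <- order(sizes, decreasing = TRUE)
  n_keep <- min(length(ord), keep)
  relab <- integer(length(sizes))
  relab[ord[seq_len(n_keep)]] <- seq_len(n_keep)
  out <- array(0L, dim(volume$data))
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  out
}

#' Compare segmented volumes with stated true volumes
#'
#' Measured volume is voxel count times voxel volume; structures are matched
#' to the supplied truths by descending size. Reports percent difference and
#' the equivalent spherical diameter `(6V/pi)^(1/3)` per structure.
#'
#' @param labels Integer label array from [threshold_segment()].
#' @param spacing Voxel size (mm, length 3).
#' @param truths_cc True volumes in cc, one per labeled structure, ordered
#'   by descending structure size.
#' @return A tibble with `structure`, `n_voxels`, `measured_cc`, `true_cc`,
#'   `percent_diff`, `equiv_diameter_mm`.
#' @export
volume_compare <- function(labels, spacing, truths_cc) {
  n_struct <- max(labels)
  if (n_struct != length(truths_cc)) {
    stop(sprintf("label map has %d structures but %d true volumes were given",
                 n_struct, length(truths_cc)))
  }
  voxel_cc <- prod(spacing) / 1000  # mm^3 -> cc
  counts <- tabulate(labels[labels > 0L], nbins = n_struct)
  measured <- counts * voxel_cc
  tibble::tibble(
    structure = seq_len(n_struct),
    n_voxels = counts,
    measured_cc = measured,
    true_cc = truths_cc,
    percent_diff = 100 * (measured - truths_cc) / truths_cc,
    equiv_diameter_mm = (6 * measured * 1000 / pi)^(1 / 3)
  )
}

#' Generate a sphere phantom volume
#'
#' Anti-aliased solid sphere, used to exercise the volumetric pipeline
#' against the analytic sphere volume.
#'
#' @param radius_mm Sphere radius (mm).
#' @param spacing Voxel size (mm).
#' @param center Sphere center (mm).
#' @param fov_mm Field of view (mm).
#' @param intensity Foreground intensity.
#' @return An [image_volume()].
#' @export
gen_sphere_volume <- function(radius_mm = 10, spacing = 1, center = c(0, 0, 0),
                              fov_mm = NULL, intensity = 1) {
  spacing <- rep_len(spacing, 3L)
  fov_mm <- fov_mm %||% (2 * radius_mm + max(abs(center)) * 2 + 10 * max(spacing))
  dims <- 2 * floor(fov_mm / 2 / spacing) + 1
  vol <- image_volume(array(0, dims), spacing = spacing)
  xyz <- vol_coords(vol)
  r <- sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
              (xyz[, 3] - center[3])^2)
  aa <- min(spacing)
  vol$data <- array(intensity * pmin(pmax(0.5 + (radius_mm - r) / aa, 0), 1), dims)
  vol$meta <- list(modality = "sphere_phantom", radius_mm = radius_mm)
  vol
}

#' Generate marker-cylinder profile phantoms
#'
#' Gaussian-blurred bead markers along a line, emulating the oil-bead marker
#' cylinders used for spatial-fidelity line-profile analysis.
#'
#' @param positions_mm Marker positions along x (mm).
#' @param sigma_mm Gaussian marker width (mm).
#' @param spacing Voxel size (mm).
#' @param fov_mm Field of view (mm).
#' @return An [image_volume()] with the markers on the x axis (y = z = 0).
#' @export
gen_marker_volume <- function(positions_mm = c(-30, 30), sigma_mm = 2,
                              spacing = 1, fov_mm = NULL) {
  spacing <- rep_len(spacing, 3L)
  fov_mm <- fov_mm %||% (2 * max(abs(positions_mm)) + 45)
  dims <- c(2 * floor(fov_mm / 2 / spacing[1]) + 1,
            2 * floor(20 / spacing[2]) + 1,
            2 * floor(20 / spacing[3]) + 1)
  vol <- image_volume(array(0, dims), spacing = spacing)
  xyz <- vol_coords(vol)
  acc <- numeric(nrow(xyz))
  for (p in positions_mm) {
    r2 <- (xyz[, 1] - p)^2 + xyz[, 2]^2 + xyz[, 3]^2
    acc <- acc + exp(-r2 / (2 * sigma_mm^2))
  }
  vol$data <- array(acc, dims)
  vol$meta <- list(modality = "marker_phantom", positions_mm = positions_mm)
  vol
}
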