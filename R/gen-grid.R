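#' Capsule-grid phantom lattice specification
#'
#' Geometry of the 3-D distortion phantom: a regular lattice of oil-capsule
#' markers with 2.5 cm centroid-to-centroid in-plane spacing and 2.7 cm
#' spacing along z, filling a 40 cm cube and trimmed to the scanner's
#' acquisition field of view (an ellipsoid with semi-axes 225 x 225 x 200 mm,
#' i.e. a 450 x 450 x 400 mm FOV). At the defaults this yields 2440 markers,
#' in line with the roughly 2500 control points of the physical phantom.
#'
#' @param in_plane_mm Centroid-to-centroid spacing in x and y (mm).
#' @param z_mm Centroid-to-centroid spacing along z (mm).
#' @param extent_mm Phantom extent per axis (mm); markers are laid out
#'   symmetrically about the isocenter within this extent.
#' @param capsule_length_mm,capsule_diameter_mm Marker capsule dimensions
#'   (mm); the capsule axis lies along x. The lattice spacing must exceed the
#'   capsule diameter.
#' @param fov_semiaxes_mm Semi-axes (mm) of the ellipsoidal scanner FOV used
#'   to trim the marker lattice; `NULL` keeps the full cube grid.
#' @param intensity_marker,intensity_background Rendered intensities (a.u.).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(in_plane_mm = 25, z_mm = 27, extent_mm = 400,
                         capsule_length_mm = 12, capsule_diameter_mm = 6,
                         fov_semiaxes_mm = c(225, 225, 200),
                         intensity_marker = 1, intensity_background = 0) {
  extent_mm <- rep_len(extent_mm, 3L)
  if (min(in_plane_mm, z_mm) <= capsule_diameter_mm) {
    stop("lattice spacing must exceed the capsule diameter")
  }
  structure(
    list(in_plane_mm = in_plane_mm, z_mm = z_mm, extent_mm = extent_mm,
         capsule_length_mm = capsule_length_mm,
         capsule_diameter_mm = capsule_diameter_mm,
         fov_semiaxes_mm = fov_semiaxes_mm,
         intensity_marker = intensity_marker,
         intensity_background = intensity_background),
    class = "lattice_spec"
  )
}

# symmetric marker positions along one axis: the largest grid whose markers
# (including their physical size) fit within the extent
lattice_axis_positions <- function(spacing, extent, marker_size = 0) {
  n <- floor((extent - marker_size) / spacing) + 1
  if (n < 1) stop("lattice extent too small for spacing")
  (seq_len(n) - (n + 1) / 2) * spacing
}

#' Marker centroid table for a lattice specification
#'
#' @param lattice A [lattice_spec()].
#' @return Tibble with 0-based lattice indices `i`, `j`, `k` and centroid
#'   coordinates `x`, `y`, `z` (mm), trimmed to the scanner FOV ellipsoid.
#'   The lattice origin (position of index 0 per axis) is stored in the
#'   `lattice_origin` attribute.
#' @export
lattice_points <- function(lattice) {
  px <- lattice_axis_positions(lattice$in_plane_mm, lattice$extent_mm[1],
                               lattice$capsule_diameter_mm)
  py <- lattice_axis_positions(lattice$in_plane_mm, lattice$extent_mm[2],
                               lattice$capsule_diameter_mm)
  pz <- lattice_axis_positions(lattice$z_mm, lattice$extent_mm[3],
                               lattice$capsule_diameter_mm)
  g <- tidyr::expand_grid(k = seq_along(pz) - 1L, j = seq_along(py) - 1L,
                          i = seq_along(px) - 1L)
  g <- tibble::tibble(i = g$i, j = g$j, k = g$k,
                      x = px[g$i + 1L], y = py[g$j + 1L], z = pz[g$k + 1L])
  if (!is.null(lattice$fov_semiaxes_mm)) {
    sa <- rep_len(lattice$fov_semiaxes_mm, 3L)
    keep <- (g$x / sa[1])^2 + (g$y / sa[2])^2 + (g$z / sa[3])^2 <= 1
    g <- g[keep, ]
  }
  attr(g, "lattice_origin") <- c(px[1], py[1], pz[1])
  attr(g, "lattice_spacing") <- c(lattice$in_plane_mm, lattice$in_plane_mm, lattice$z_mm)
  g
}

# render solid capsules (axis along x) into an array with true partial-volume
# weighting: each voxel's intensity is the fraction of the voxel inside the
# capsule, estimated by nss^3 sub-voxel samples. This keeps the
# intensity-weighted centroid of a rendered capsule sub-voxel accurate
# (a few hundredths of a millimetre at 2 mm voxels).
render_capsules <- function(vol, centers, length_mm, diameter_mm, intensity,
                            nss = 3) {
  radius <- diameter_mm / 2
  half_seg <- max(length_mm / 2 - radius, 0)
  sp <- vol$spacing
  xc <- vol_axis_coords(vol, 1); yc <- vol_axis_coords(vol, 2); zc <- vol_axis_coords(vol, 3)
  off <- (seq_len(nss) - (nss + 1) / 2) / nss  # sub-voxel center offsets
  pad <- radius + half_seg + max(sp)
  for (m in seq_len(nrow(centers))) {
    cx <- centers[m, 1]; cy <- centers[m, 2]; cz <- centers[m, 3]
    ix <- which(xc >= cx - pad & xc <= cx + pad)
    iy <- which(yc >= cy - pad & yc <= cy + pad)
    iz <- which(zc >= cz - pad & zc <= cz + pad)
    if (!length(ix) || !length(iy) || !length(iz)) next
    acc <- array(0, c(length(ix), length(iy), length(iz)))
    for (ox in off) for (oy in off) for (oz in off) {
      ax <- pmin(pmax(xc[ix] + ox * sp[1] - cx, -half_seg), half_seg)
      dx <- xc[ix] + ox * sp[1] - cx - ax
      dyz2 <- outer((yc[iy] + oy * sp[2] - cy)^2, (zc[iz] + oz * sp[3] - cz)^2, "+")
      acc <- acc + array(outer(dx^2, as.vector(dyz2), "+") <= radius^2, dim(acc))
    }
    vol$data[ix, iy, iz] <- pmax(vol$data[ix, iy, iz],
                                 intensity * acc / nss^3)
  }
  vol
}

#' Generate a reference/distorted grid-phantom image pair with ground truth
#'
#' Renders the capsule-grid phantom twice: once with markers at the exact
#' lattice centroids (the "CT" reference role) and once with every marker
#' displaced by a [distortion_model()] (the "MR" role). The returned truth
#' table lists every marker centroid with its true displacement vector, which
#' is the oracle for the distortion-mapping pipeline.
#'
#' @param lattice A [lattice_spec()].
#' @param model A [distortion_model()]; the default zero model makes the two
#'   volumes identical.
#' @param noise_sd Gaussian intensity noise standard deviation (a.u.) added
#'   to both volumes.
#' @param seed Integer seed for the noise; required for reproducibility when
#'   `noise_sd > 0`.
#' @param spacing Rendered voxel size (mm), default 2 mm isotropic.
#' @param margin_mm Empty margin around the marker FOV (mm).
#' @return A list with elements `reference` and `distorted`
#'   ([image_volume()]s) and `truth`, a tibble with lattice indices,
#'   reference centroids `x`, `y`, `z`, displacement components `dx`, `dy`,
#'   `dz`, magnitude `d_mag` and an `ambiguous` flag set where the
#'   displacement exceeds half the lattice spacing (nearest-marker matching
#'   is then no longer guaranteed unique).
#' @examples
#' pair <- gen_grid_phantom_pair(lattice_spec(extent_mm = 100,
#'                                            fov_semiaxes_mm = NULL),
#'                               spacing = 2.5)
#' nrow(pair$truth)
#' @export
gen_grid_phantom_pair <- function(lattice = lattice_spec(),
                                  model = distortion_model(),
                                  noise_sd = 0, seed = NULL,
                                  spacing = c(2, 2, 2), margin_mm = 15) {
  pts <- lattice_points(lattice)
  centers <- cbind(pts$x, pts$y, pts$z)
  disp <- evaluate_distortion(model, centers)
  half_spacing <- min(lattice$in_plane_mm, lattice$z_mm) / 2
  d_mag <- sqrt(rowSums(disp^2))
  truth <- tibble::tibble(
    i = pts$i, j = pts$j, k = pts$k,
    x = pts$x, y = pts$y, z = pts$z,
    dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
    d_mag = d_mag,
    ambiguous = d_mag > half_spacing
  )
  if (any(truth$ambiguous)) {
    warn(sprintf("%d marker displacement(s) exceed half the lattice spacing; matching may be ambiguous",
                 sum(truth$ambiguous)))
  }
  spacing <- rep_len(spacing, 3L)
  lim <- apply(abs(rbind(centers, centers + disp)), 2, max) +
    lattice$capsule_length_mm / 2 + margin_mm
  dims <- 2 * ceiling(lim / spacing) + 1
  blank <- image_volume(array(lattice$intensity_background, dims), spacing = spacing)
  reference <- render_capsules(blank, centers, lattice$capsule_length_mm,
                               lattice$capsule_diameter_mm, lattice$intensity_marker)
  distorted <- render_capsules(blank, centers + disp, lattice$capsule_length_mm,
                               lattice$capsule_diameter_mm, lattice$intensity_marker)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    reference$data <- reference$data + array(stats::rnorm(length(reference$data), 0, noise_sd), dims)
    distorted$data <- distorted$data + array(stats::rnorm(length(distorted$data), 0, noise_sd), dims)
  }
  reference$meta <- list(modality = "grid_phantom", role = "reference")
  distorted$meta <- list(modality = "grid_phantom", role = "distorted")
  attr(truth, "lattice_origin") <- attr(pts, "lattice_origin")
  attr(truth, "lattice_spacing") <- attr(pts, "lattice_spacing")
  list(reference = reference, distorted = distorted, truth = truth)
}

#' Write a control-point / displacement truth table to CSV
#'
#' @param truth A truth or displacement tibble (lattice indices, reference
#'   coordinates and displacement components).
#' @param path Output CSV path.
#' @export
write_control_points <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
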