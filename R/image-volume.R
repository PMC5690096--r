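#' Create an image volume
#'
#' A light container for a 3-D scalar image on a regular grid with physical
#' voxel spacing in millimetres. The coordinate frame is shared by every
#' generator and analysis in the package: physical mm, origin at the magnet
#' isocenter, voxel-center convention. The physical coordinate of voxel
#' `(i, j, k)` (1-based R indices) is `origin + (c(i, j, k) - 1) * spacing`.
#' Axis labels follow the scanner convention x = right-left,
#' y = anterior-posterior, z = foot-head.
#'
#' @param data Numeric 3-D array (a matrix is promoted to a single-slice
#'   volume). All values must be finite.
#' @param spacing Per-axis voxel size in mm, length 3 (or scalar, recycled).
#'   Must be positive.
#' @param origin Physical coordinate (mm) of the center of voxel `(1, 1, 1)`,
#'   or the string `"center"` (default) to center the grid on the isocenter.
#' @param meta Named list of free-form metadata (modality, echo time, masks).
#'
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing`, `origin`, `axes` and `meta`.
#' @examples
#' vol <- image_volume(array(0, c(16, 16, 8)), spacing = c(2, 2, 5))
#' vol_axis_coords(vol, 3)
#' @export
image_volume <- function(data, spacing, origin = "center", meta = list()) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("image data must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (identical(origin, "center")) {
    origin <- -(dim(data) - 1) / 2 * spacing
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         axes = c("x", "y", "z"), meta = meta),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm; intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) <= 3, TRUE)
    if (any(keep)) {
      cat("  meta:", paste(names(x$meta)[keep],
                           vapply(x$meta[keep], function(v) paste(format(v), collapse = ","), ""),
                           sep = "=", collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param vol An [image_volume()].
#' @param axis Axis index (1 = x, 2 = y, 3 = z) or label.
#' @return Numeric vector of physical voxel-center positions in mm.
#' @export
vol_axis_coords <- function(vol, axis) {
  if (is.character(axis)) axis <- match(axis, vol$axes)
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

#' Physical coordinates of every voxel center
#'
#' @inheritParams vol_axis_coords
#' @return A 3-column matrix (`x`, `y`, `z`) with one row per voxel in R's
#'   column-major order, matching `as.vector(vol$data)`.
#' @export
vol_coords <- function(vol) {
  d <- dim(vol$data)
  cbind(
    x = rep(vol_axis_coords(vol, 1), times = d[2] * d[3]),
    y = rep(rep(vol_axis_coords(vol, 2), each = d[1]), times = d[3]),
    z = rep(vol_axis_coords(vol, 3), each = d[1] * d[2])
  )
}

#' Radial distance of every voxel center from the isocenter
#' @inheritParams vol_axis_coords
#' @return Numeric array of distances (mm), same shape as `vol$data`.
#' @export
vol_radius <- function(vol) {
  xc <- vol_axis_coords(vol, 1); yc <- vol_axis_coords(vol, 2); zc <- vol_axis_coords(vol, 3)
  d <- dim(vol$data)
  r2 <- outer(outer(xc^2, yc^2, "+"), zc^2, "+")
  array(sqrt(r2), d)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Sample a volume along a line by trilinear interpolation
#'
#' @param vol An [image_volume()].
#' @param points An n x 3 matrix of physical coordinates (mm).
#' @return Numeric vector of interpolated intensities; `NA` outside the grid.
#' @export
vol_interp <- function(vol, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(vol$data)
  # continuous (1-based) voxel index per axis
  u <- sweep(sweep(points, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  i0 <- floor(u)
  for (ax in 1:3) {
    i0[, ax] <- pmin(pmax(i0[, ax], 1), max(d[ax] - 1, 1))
  }
  fr <- u - i0
  out <- numeric(nrow(points))
  inside <- u[, 1] >= 1 & u[, 1] <= d[1] & u[, 2] >= 1 & u[, 2] <= d[2] &
    u[, 3] >= 1 & u[, 3] <= d[3]
  acc <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (cz == 1) fr[, 3] else 1 - fr[, 3])
    ii <- pmin(i0[, 1] + cx, d[1]); jj <- pmin(i0[, 2] + cy, d[2]); kk <- pmin(i0[, 3] + cz, d[3])
    acc <- acc + w * vol$data[cbind(ii, jj, kk)]
  }
  out[] <- NA_real_
  out[inside] <- acc[inside]
  out
}

#' Write / read an image volume as NIfTI-1
#'
#' The affine is diagonal, built from the voxel spacing with the translation
#' set so that voxel `(1,1,1)` maps to `origin` (isocenter-centered frame).
#'
#' @param vol An [image_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xform <- diag(c(vol$spacing, 1))
  xform[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(xform, code = 2L)
  RNifti::qform(img) <- structure(xform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_volume(arr, spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

#' Plot an axial slice of a volume
#'
#' @param object An [image_volume()].
#' @param slice Slice index along z (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.image_volume <- function(object, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(object$data)[3] / 2)
  df <- tibble::tibble(
    x = rep(vol_axis_coords(object, 1), times = dim(object$data)[2]),
    y = rep(vol_axis_coords(object, 2), each = dim(object$data)[1]),
    intensity = as.vector(object$data[, , slice])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "a.u.")
}
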