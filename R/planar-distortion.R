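#' Planar (2-D) distortion analysis with compliant rectangle
#'
#' Daily-QA style in-plane distortion analysis. The displacement magnitudes
#' of the control points in one plane are interpolated bilinearly over the
#' marker lattice to a dense map, isocontours are extracted at 2-6 mm, and a
#' compliant rectangle is derived: axis-aligned, centered at the isocenter,
#' grown alternately in each axis by one lattice step for as long as at
#' least `fraction` of the enclosed control points have displacement below
#' `threshold_mm`. The recorded rectangle dimensions mirror the routine QA
#' readout of the region where more than 75% of the distortion is under 2 mm.
#'
#' @param field A `displacement_field` restricted to a single marker plane
#'   (e.g. `dplyr::filter(field, k == 7)` for the axial plane through the
#'   isocenter). At least 4 points are required.
#' @param plane `"axial"` (x-y), `"sagittal"` (y-z) or `"coronal"` (x-z);
#'   selects the two in-plane axes.
#' @param grid_step_mm Sampling step of the dense interpolated map (mm).
#' @param threshold_mm,fraction Compliance rule: the rectangle keeps at least
#'   `fraction` of enclosed points under `threshold_mm` of displacement.
#' @param contour_levels Isocontour levels (mm).
#' @return An object of class `planar_distortion`: a list with `dense`
#'   (tibble `u`, `v`, `d_mag`), `contours` (tibble `level`, `piece`, `u`,
#'   `v`), `rectangle` (list with `center`, `width_mm`, `height_mm`),
#'   `points` (the in-plane control points), and `axes` (the in-plane axis
#'   labels).
#' @export
planar_distortion_analysis <- function(field, plane = "axial",
                                       grid_step_mm = 2, threshold_mm = 2,
                                       fraction = 0.75, contour_levels = 2:6) {
  ax <- switch(plane, axial = c("x", "y"), sagittal = c("y", "z"),
               coronal = c("x", "z"), stop("unknown plane: ", plane))
  if (nrow(field) < 4) stop("need at least 4 in-plane control points")
  u <- field[[ax[1]]]
  v <- field[[ax[2]]]
  d <- field$d_mag
  uu <- sort(unique(u)); vv <- sort(unique(v))
  zmat <- matrix(NA_real_, length(uu), length(vv))
  zmat[cbind(match(u, uu), match(v, vv))] <- d

  # dense bilinear interpolation over the lattice cells
  ud <- seq(min(uu), max(uu), by = grid_step_mm)
  vd <- seq(min(vv), max(vv), by = grid_step_mm)
  iu <- pmin(findInterval(ud, uu), length(uu) - 1)
  iv <- pmin(findInterval(vd, vv), length(vv) - 1)
  fu <- (ud - uu[iu]) / (uu[iu + 1] - uu[iu])
  fv <- (vd - vv[iv]) / (vv[iv + 1] - vv[iv])
  dense <- outer(seq_along(ud), seq_along(vd), function(a, b) {
    (1 - fu[a]) * (1 - fv[b]) * zmat[cbind(iu[a], iv[b])] +
      fu[a] * (1 - fv[b]) * zmat[cbind(iu[a] + 1, iv[b])] +
      (1 - fu[a]) * fv[b] * zmat[cbind(iu[a], iv[b] + 1)] +
      fu[a] * fv[b] * zmat[cbind(iu[a] + 1, iv[b] + 1)]
  })
  dense_tbl <- tibble::tibble(u = rep(ud, times = length(vd)),
                              v = rep(vd, each = length(ud)),
                              d_mag = as.vector(dense))

  cl <- grDevices::contourLines(uu, vv, zmat, levels = contour_levels)
  contours <- purrr::imap_dfr(cl, function(cc, piece) {
    tibble::tibble(level = cc$level, piece = piece, u = cc$x, v = cc$y)
  })
  if (!nrow(contours)) {
    contours <- tibble::tibble(level = numeric(), piece = integer(),
                               u = numeric(), v = numeric())
  }

  # compliant rectangle: symmetric expansion about the isocenter
  eps <- 1e-9
  hu_levels <- sort(unique(abs(u))) + eps
  hv_levels <- sort(unique(abs(v))) + eps
  compliant <- function(hu, hv) {
    inside <- abs(u) <= hu & abs(v) <= hv
    if (!any(inside)) return(TRUE)
    mean(d[inside] < threshold_mm) >= fraction
  }
  cu <- 1L; cv <- 1L
  if (!compliant(hu_levels[cu], hv_levels[cv])) {
    warn("distortion exceeds the compliance rule already at the innermost lattice step")
  }
  stuck_u <- cu >= length(hu_levels); stuck_v <- cv >= length(hv_levels)
  while (!(stuck_u && stuck_v)) {
    if (!stuck_u) {
      if (compliant(hu_levels[cu + 1L], hv_levels[cv])) cu <- cu + 1L else stuck_u <- TRUE
      if (cu >= length(hu_levels)) stuck_u <- TRUE
    }
    if (!stuck_v) {
      if (compliant(hu_levels[cu], hv_levels[cv + 1L])) cv <- cv + 1L else stuck_v <- TRUE
      if (cv >= length(hv_levels)) stuck_v <- TRUE
    }
  }
  rect <- list(center = c(0, 0),
               width_mm = 2 * (hu_levels[cu] - eps),
               height_mm = 2 * (hv_levels[cv] - eps))

  structure(
    list(dense = dense_tbl, contours = contours, rectangle = rect,
         points = tibble::tibble(u = u, v = v, d_mag = d),
         axes = ax, threshold_mm = threshold_mm, fraction = fraction),
    class = "planar_distortion"
  )
}

#' @export
print.planar_distortion <- function(x, ...) {
  cat("<planar_distortion>\n")
  cat(sprintf("  axes: %s-%s; %d control points\n", x$axes[1], x$axes[2],
              nrow(x$points)))
  cat(sprintf("  compliant rectangle (>=%.0f%% of points < %g mm): %.1f x %.1f mm\n",
              100 * x$fraction, x$threshold_mm,
              x$rectangle$width_mm, x$rectangle$height_mm))
  invisible(x)
}

#' @export
glance.planar_distortion <- function(x, ...) {
  tibble::tibble(width_mm = x$rectangle$width_mm,
                 height_mm = x$rectangle$height_mm,
                 n_points = nrow(x$points),
                 max_d_mag = max(x$points$d_mag))
}

#' Plot a planar distortion analysis
#'
#' Dense displacement-magnitude map with isocontours and the compliant
#' rectangle overlaid.
#'
#' @param object A `planar_distortion` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.planar_distortion <- function(object, ...) {
  r <- object$rectangle
  p <- ggplot2::ggplot(object$dense, ggplot2::aes(.data$u, .data$v)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$d_mag)) +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::annotate("rect", xmin = -r$width_mm / 2, xmax = r$width_mm / 2,
                      ymin = -r$height_mm / 2, ymax = r$height_mm / 2,
                      colour = "white", fill = NA, linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(object$axes[1], " (mm)"),
                  y = paste0(object$axes[2], " (mm)"),
                  fill = "|d| (mm)")
  if (nrow(object$contours)) {
    p <- p + ggplot2::geom_path(
      data = object$contours,
      ggplot2::aes(group = .data$piece), colour = "grey30", linewidth = 0.3)
  }
  p
}

#' @export
tidy.displacement_field <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.displacement_field <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x),
    n_unmatched = nrow(attr(x, "unmatched") %||% tibble::tibble()),
    mean_mm = mean(x$d_mag),
    rms_mm = sqrt(mean(x$d_mag^2)),
    max_mm = max(x$d_mag)
  )
}

#' Quiver-style plot of a displacement field
#'
#' @param object A `displacement_field`.
#' @param plane Projection plane, as in [planar_distortion_analysis()].
#' @param scale Arrow magnification factor for visibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.displacement_field <- function(object, plane = "axial", scale = 10, ...) {
  ax <- switch(plane, axial = c("x", "y"), sagittal = c("y", "z"),
               coronal = c("x", "z"))
  dax <- paste0("d", ax)
  df <- tibble::tibble(u = object[[ax[1]]], v = object[[ax[2]]],
                       du = object[[dax[1]]], dv = object[[dax[2]]],
                       d_mag = object$d_mag)
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$u + scale * .data$du,
                   yend = .data$v + scale * .data$dv,
                   colour = .data$d_mag),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (mm)"), y = paste0(ax[2], " (mm)"),
                  colour = "|d| (mm)")
}
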