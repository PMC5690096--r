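#' Detect grid-phantom markers by connected-component centroid analysis
#'
#' Thresholds the volume at a fraction of its maximum intensity, labels
#' connected components in 3-D (26-connectivity), discards small components,
#' and returns the intensity-weighted center of mass of each component in
#' physical mm. When the lattice geometry is supplied, each centroid is
#' assigned the 0-based lattice index obtained by rounding
#' `(centroid - lattice_origin) / lattice_spacing`; if two components round
#' to the same index the larger-mass component is kept and the collision
#' reported.
#'
#' @param volume An [image_volume()] with bimodal foreground/background.
#' @param intensity_threshold Segmentation threshold as a fraction of the
#'   maximum intensity (default 0.5); defines the connected components.
#' @param min_voxels Minimum component size in voxels.
#' @param lattice Optional [lattice_spec()] (or a truth table carrying
#'   `lattice_origin`/`lattice_spacing` attributes) used to assign lattice
#'   indices.
#' @param com_threshold Lower threshold (fraction of maximum) for the
#'   center-of-mass computation: around each component the partial-volume
#'   shell above this level (within a 2-voxel margin of the component's
#'   bounding box) is included, which keeps the centroid continuous under
#'   sub-voxel translations of the marker.
#' @return A tibble of control points: lattice indices `i`, `j`, `k` (`NA`
#'   without lattice), centroids `x`, `y`, `z` (mm), `mass` and `n_voxels`.
#'   Collisions, if any, are stored in the `collisions` attribute.
#' @export
detect_markers <- function(volume, intensity_threshold = 0.5, min_voxels = 4,
                           lattice = NULL, com_threshold = 0.05) {
  vmax <- max(volume$data)
  mask <- volume$data > intensity_threshold * vmax
  if (!any(mask)) {
    return(tibble::tibble(i = integer(), j = integer(), k = integer(),
                          x = numeric(), y = numeric(), z = numeric(),
                          mass = numeric(), n_voxels = integer()))
  }
  lab <- .cc_label3d(mask, dim(volume$data), 26L)
  nvox_all <- tabulate(lab[lab > 0L])
  keep_lab <- which(nvox_all >= min_voxels)
  if (!length(keep_lab)) {
    return(tibble::tibble(i = integer(), j = integer(), k = integer(),
                          x = numeric(), y = numeric(), z = numeric(),
                          mass = numeric(), n_voxels = integer()))
  }
  d <- dim(volume$data)
  idx <- which(lab > 0L & array(lab %in% keep_lab, d))
  ai <- arrayInd(idx, d)
  lv <- lab[idx]
  lo <- com_threshold * vmax
  xc <- vol_axis_coords(volume, 1)
  yc <- vol_axis_coords(volume, 2)
  zc <- vol_axis_coords(volume, 3)
  res <- purrr::map_dfr(keep_lab, function(lb) {
    sel <- lv == lb
    bb <- ai[sel, , drop = FALSE]
    ix <- max(1, min(bb[, 1]) - 2):min(d[1], max(bb[, 1]) + 2)
    iy <- max(1, min(bb[, 2]) - 2):min(d[2], max(bb[, 2]) + 2)
    iz <- max(1, min(bb[, 3]) - 2):min(d[3], max(bb[, 3]) + 2)
    block <- volume$data[ix, iy, iz, drop = FALSE]
    w <- ifelse(block > lo, block, 0)
    mass <- sum(w)
    tibble::tibble(
      x = sum(w * rep(xc[ix], times = length(iy) * length(iz))) / mass,
      y = sum(w * rep(rep(yc[iy], each = length(ix)), times = length(iz))) / mass,
      z = sum(w * rep(zc[iz], each = length(ix) * length(iy))) / mass,
      mass = mass, n_voxels = sum(sel)
    )
  })
  pts <- tibble::tibble(i = NA_integer_, j = NA_integer_, k = NA_integer_,
                        x = res$x, y = res$y, z = res$z,
                        mass = res$mass, n_voxels = as.integer(res$n_voxels))
  collisions <- NULL
  if (!is.null(lattice)) {
    if (inherits(lattice, "lattice_spec")) {
      org <- attr(lattice_points(lattice), "lattice_origin")
      sp <- c(lattice$in_plane_mm, lattice$in_plane_mm, lattice$z_mm)
    } else {
      org <- attr(lattice, "lattice_origin")
      sp <- attr(lattice, "lattice_spacing")
    }
    pts$i <- as.integer(round((pts$x - org[1]) / sp[1]))
    pts$j <- as.integer(round((pts$y - org[2]) / sp[2]))
    pts$k <- as.integer(round((pts$z - org[3]) / sp[3]))
    key <- paste(pts$i, pts$j, pts$k)
    if (anyDuplicated(key)) {
      dup_keys <- unique(key[duplicated(key)])
      collisions <- pts[key %in% dup_keys, ]
      pts <- pts[order(-pts$mass), ]
      pts <- pts[!duplicated(paste(pts$i, pts$j, pts$k)), ]
      pts <- pts[order(pts$k, pts$j, pts$i), ]
      warn(sprintf("%d lattice index collision(s); kept the larger-mass component",
                   length(dup_keys)))
    }
  }
  attr(pts, "collisions") <- collisions
  pts
}

#' Rigid (Kabsch) pre-alignment of measured control points
#'
#' Fits the rigid transform (rotation + translation, no scaling) that maps
#' measured centroids onto their reference counterparts, using only markers
#' within `fit_radius_mm` of the isocenter, where system distortion is
#' smallest, so that the distortion being measured is not absorbed into the
#' rigid fit. Points are paired by nearest neighbour within `max_radius_mm`.
#'
#' @param reference,measured Control-point tibbles (from [detect_markers()]
#'   or [lattice_points()]).
#' @param fit_radius_mm Radius of the central fitting region (default 50 mm).
#' @param max_radius_mm Pairing radius for the fit (default half the smallest
#'   point spacing is a sensible choice; 12 mm by default).
#' @return A list with the 3 x 3 rotation `R`, translation `t` (mm, applied
#'   as `p %*% R + t`), the aligned `measured` tibble, and the fit RMS (mm).
#' @export
align_rigid <- function(reference, measured, fit_radius_mm = 50,
                        max_radius_mm = 12) {
  rc <- reference[sqrt(reference$x^2 + reference$y^2 + reference$z^2) <= fit_radius_mm, ]
  mc <- measured[sqrt(measured$x^2 + measured$y^2 + measured$z^2) <=
                   fit_radius_mm + max_radius_mm, ]
  if (nrow(rc) < 3 || nrow(mc) < 3) stop("not enough central markers for a rigid fit")
  pairs <- greedy_match(cbind(rc$x, rc$y, rc$z), cbind(mc$x, mc$y, mc$z), max_radius_mm)
  if (nrow(pairs) < 3) stop("not enough central marker pairs for a rigid fit")
  P <- cbind(mc$x, mc$y, mc$z)[pairs$measured, , drop = FALSE]  # moving
  Q <- cbind(rc$x, rc$y, rc$z)[pairs$reference, , drop = FALSE] # fixed
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tvec <- cq - as.vector(cp %*% R)
  aligned <- measured
  xyz <- cbind(measured$x, measured$y, measured$z) %*% R
  aligned$x <- xyz[, 1] + tvec[1]
  aligned$y <- xyz[, 2] + tvec[2]
  aligned$z <- xyz[, 3] + tvec[3]
  rms <- sqrt(mean(rowSums((P %*% R + matrix(tvec, nrow(P), 3, byrow = TRUE) - Q)^2)))
  list(R = R, t = tvec, measured = aligned, fit_rms_mm = rms,
       n_pairs = nrow(pairs))
}

# one-to-one greedy nearest matching: candidate pairs sorted by ascending
# distance (ties broken by row order, i.e. lattice lexicographic order when
# the inputs are lattice-sorted); returns reference/measured row indices
greedy_match <- function(ref_xyz, meas_xyz, max_radius) {
  if (!nrow(ref_xyz) || !nrow(meas_xyz)) {
    return(tibble::tibble(reference = integer(), measured = integer(),
                          dist = numeric()))
  }
  d2 <- outer(rowSums(ref_xyz^2), rowSums(meas_xyz^2), "+") -
    2 * ref_xyz %*% t(meas_xyz)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= max_radius^2, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble::tibble(reference = integer(), measured = integer(),
                          dist = numeric()))
  }
  dd <- sqrt(d2[cand])
  ord <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  used_r <- logical(nrow(ref_xyz)); used_m <- logical(nrow(meas_xyz))
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    r <- cand[q, 1]; m <- cand[q, 2]
    if (!used_r[r] && !used_m[m]) {
      keep[q] <- TRUE; used_r[r] <- TRUE; used_m[m] <- TRUE
    }
  }
  tibble::tibble(reference = cand[keep, 1], measured = cand[keep, 2],
                 dist = dd[keep])
}

#' Match measured control points to reference points
#'
#' Pairs each reference point with the nearest measured point within
#' `max_radius_mm`, one-to-one, greedily by ascending pair distance (ties by
#' lattice lexicographic order). Reference points left unpaired are reported
#' as unmatched. Both sets must already be in the same physical frame; use
#' [align_rigid()] first when the acquisition was not pre-registered.
#'
#' @param reference,measured Control-point tibbles.
#' @param max_radius_mm Maximum pairing distance (mm). A warning is issued
#'   when this exceeds half the lattice spacing implied by the reference set,
#'   since matching can then be ambiguous.
#' @return A tibble of class `displacement_field`: lattice indices and
#'   reference coordinates `x`, `y`, `z`, measured coordinates `x_meas`,
#'   `y_meas`, `z_meas`, displacement `dx`, `dy`, `dz` (measured - reference,
#'   mm) and magnitude `d_mag`. Unmatched reference points are kept in the
#'   `unmatched` attribute.
#' @export
match_control_points <- function(reference, measured, max_radius_mm = 12) {
  pairs <- greedy_match(cbind(reference$x, reference$y, reference$z),
                        cbind(measured$x, measured$y, measured$z),
                        max_radius_mm)
  r <- reference[pairs$reference, ]
  m <- measured[pairs$measured, ]
  out <- tibble::tibble(
    i = r$i, j = r$j, k = r$k,
    x = r$x, y = r$y, z = r$z,
    x_meas = m$x, y_meas = m$y, z_meas = m$z,
    dx = m$x - r$x, dy = m$y - r$y, dz = m$z - r$z
  )
  out$d_mag <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  unmatched <- reference[setdiff(seq_len(nrow(reference)), pairs$reference), ]
  structure(out, unmatched = unmatched,
            class = c("displacement_field", class(out)))
}

#' Radial shell summary of a displacement field
#'
#' Bins matched control points by the radial distance of their *reference*
#' position from the isocenter and summarizes the displacement magnitude per
#' shell: mean, population standard deviation, maximum, and the fraction of
#' points with displacement in the 2-3 mm band and at or above 3 mm. The
#' default shells are the 0-5 cm sphere and the 5-10, 10-15 and 15-20 cm
#' annuli. Empty shells report `NA` metrics (not zero).
#'
#' @param field A `displacement_field` from [match_control_points()].
#' @param shell_edges_mm Increasing vector of shell boundaries (mm).
#' @return A tibble with one row per shell: `r_min`, `r_max`, `n`,
#'   `mean_mm`, `sd_mm`, `max_mm`, `frac_2_3mm`, `frac_ge_3mm`.
#' @export
radial_distortion_summary <- function(field, shell_edges_mm = c(0, 50, 100, 150, 200)) {
  if (!nrow(field)) stop("displacement field is empty")
  r <- sqrt(field$x^2 + field$y^2 + field$z^2)
  shell_of_point <- cut(r, shell_edges_mm, include.lowest = TRUE, right = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stats <- purrr::map_dfr(levels(shell_of_point), function(s) {
    d <- field$d_mag[!is.na(shell_of_point) & shell_of_point == s]
    if (!length(d)) {
      return(tibble::tibble(n = 0L, mean_mm = NA_real_, sd_mm = NA_real_,
                            max_mm = NA_real_, frac_2_3mm = NA_real_,
                            frac_ge_3mm = NA_real_))
    }
    tibble::tibble(n = length(d), mean_mm = mean(d), sd_mm = pop_sd(d),
                   max_mm = max(d), frac_2_3mm = mean(d >= 2 & d < 3),
                   frac_ge_3mm = mean(d >= 3))
  })
  dplyr::bind_cols(
    tibble::tibble(r_min = shell_edges_mm[-length(shell_edges_mm)],
                   r_max = shell_edges_mm[-1]),
    stats
  )
}

#' End-to-end 3-D distortion mapping from an image pair
#'
#' Convenience chain: detect markers in both volumes, rigidly pre-align the
#' measured set using the central markers, match control points one-to-one
#' and summarize by radial shell.
#'
#' @param reference,measured [image_volume()]s of the grid phantom.
#' @param lattice The [lattice_spec()] used for index assignment.
#' @param align Logical: perform the central-sphere rigid pre-alignment
#'   (default `TRUE`).
#' @param intensity_threshold,min_voxels Passed to [detect_markers()].
#' @param max_radius_mm Passed to [match_control_points()].
#' @param shell_edges_mm Passed to [radial_distortion_summary()].
#' @return A list with `field` (the `displacement_field`), `summary` (the
#'   shell tibble), and `alignment` (the rigid fit, or `NULL`).
#' @export
map_distortion_3d <- function(reference, measured, lattice = lattice_spec(),
                              align = TRUE, intensity_threshold = 0.5,
                              min_voxels = 4, max_radius_mm = 12,
                              shell_edges_mm = c(0, 50, 100, 150, 200)) {
  ref_pts <- detect_markers(reference, intensity_threshold, min_voxels, lattice)
  mea_pts <- detect_markers(measured, intensity_threshold, min_voxels, lattice)
  alignment <- NULL
  if (align) {
    alignment <- align_rigid(ref_pts, mea_pts)
    mea_pts <- alignment$measured
  }
  field <- match_control_points(ref_pts, mea_pts, max_radius_mm)
  list(field = field,
       summary = radial_distortion_summary(field, shell_edges_mm),
       alignment = alignment)
}
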