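#' Parametric ppm inhomogeneity fields
#'
#' Constructors for programmed main-field deviation maps used by
#' [gen_phase_pair()]. `ppm_parabolic()` is the canonical smooth test field:
#' deviation grows quadratically with the distance from the isocenter and
#' reaches `peak_ppm` at `radius_mm`.
#'
#' @param peak_ppm Deviation (ppm) at `radius_mm`.
#' @param radius_mm Radius at which the peak is reached (mm).
#' @return A function mapping an n x 3 coordinate matrix (mm) to ppm values.
#' @export
ppm_parabolic <- function(peak_ppm, radius_mm = 155) {
  force(peak_ppm); force(radius_mm)
  function(xyz) peak_ppm * rowSums(xyz^2) / radius_mm^2
}

#' Generate a dual-echo phase-image pair of a uniform sphere phantom
#'
#' Simulates the ACR-style field-homogeneity acquisition: a uniform 31 cm
#' sphere imaged with a gradient-echo sequence at two echo times. The phase
#' at echo time `TE` is `wrap(2*pi * f0 * ppm*1e-6 * TE + phi0)` in
#' `[-pi, pi)`, so the phase difference between the echoes encodes the field
#' deviation. The returned truth is the programmed ppm field over the sphere.
#'
#' @param ppm_field Function mapping an n x 3 mm coordinate matrix to ppm
#'   (e.g. [ppm_parabolic()]), or a numeric array matching the grid.
#' @param te1_ms,te2_ms Echo times (ms), `te2_ms > te1_ms`.
#' @param f0_hz Central frequency (Hz).
#' @param noise_sd Phase noise standard deviation (radians).
#' @param seed Integer seed for the noise.
#' @param phi0 Spatially constant receiver phase offset (radians).
#' @param recon_fov_mm Reconstruction field of view (mm); the image grid.
#' @param spacing Voxel size (mm).
#' @param sphere_diameter_mm Diameter of the uniform sphere phantom (mm).
#' @return A list with `phase1`, `phase2` ([image_volume()]s with
#'   `meta$te_ms` and `meta$mask`) and `truth` (an [image_volume()] of ppm
#'   with the sphere mask in `meta$mask`).
#' @export
gen_phase_pair <- function(ppm_field, te1_ms = 10, te2_ms = 12,
                           f0_hz = 42587276, noise_sd = 0, seed = NULL,
                           phi0 = 0.3, recon_fov_mm = 350,
                           spacing = c(3.5, 3.5, 5),
                           sphere_diameter_mm = 310) {
  if (te2_ms <= te1_ms) stop("te2_ms must exceed te1_ms")
  spacing <- rep_len(spacing, 3L)
  dims <- 2 * floor(recon_fov_mm / 2 / spacing) + 1
  blank <- image_volume(array(0, dims), spacing = spacing)
  xyz <- vol_coords(blank)
  r <- sqrt(rowSums(xyz^2))
  mask <- array(r <= sphere_diameter_mm / 2, dims)
  ppm <- if (is.function(ppm_field)) ppm_field(xyz) else as.vector(ppm_field)
  ppm <- array(ppm, dims)
  ppm[!mask] <- 0

  # Itoh condition on the echo-difference phase: adjacent-voxel increments
  # must stay below pi or unwrapping the difference map is ill-posed
  dte_s <- (te2_ms - te1_ms) * 1e-3
  dphi <- 2 * pi * f0_hz * ppm * 1e-6 * dte_s
  nd <- dim(dphi)
  max_step <- max(
    abs(dphi[-1, , , drop = FALSE] - dphi[-nd[1], , , drop = FALSE]),
    abs(dphi[, -1, , drop = FALSE] - dphi[, -nd[2], , drop = FALSE]),
    abs(dphi[, , -1, drop = FALSE] - dphi[, , -nd[3], drop = FALSE])
  )
  if (max_step >= pi) {
    stop(sprintf("adjacent-voxel phase-difference step %.2f rad >= pi: unwrapping ill-posed (Itoh condition)",
                 max_step))
  }

  if (!is.null(seed)) set.seed(seed)
  mk_phase <- function(te_ms) {
    phi <- 2 * pi * f0_hz * ppm * 1e-6 * te_ms * 1e-3 + phi0
    if (noise_sd > 0) phi <- phi + array(stats::rnorm(length(phi), 0, noise_sd), dims)
    out <- blank
    out$data <- wrap_phase(phi)
    out$meta <- list(kind = "phase", te_ms = te_ms, f0_hz = f0_hz, mask = mask)
    out
  }
  p1 <- mk_phase(te1_ms)
  p2 <- mk_phase(te2_ms)
  truth <- blank
  truth$data <- ppm
  truth$meta <- list(kind = "ppm", mask = mask,
                     dsv_mm = sphere_diameter_mm, f0_hz = f0_hz)
  list(phase1 = p1, phase2 = p2, truth = truth)
}

#' Wrapped phase-difference map between two echoes
#'
#' Subtracts the first-echo phase image from the second and wraps the result
#' into `[-pi, pi)`. The echo-time difference is carried on the output.
#'
#' @param p1,p2 Phase [image_volume()]s on the same grid, `meta$te_ms` set,
#'   with `p2` the later echo.
#' @return A phase [image_volume()] with `meta$dte_ms` and the intersected
#'   validity mask.
#' @export
phase_difference_map <- function(p1, p2) {
  if (!same_grid(p1, p2)) stop("phase images are not on the same grid")
  if (is.null(p1$meta$te_ms) || is.null(p2$meta$te_ms) ||
      p2$meta$te_ms <= p1$meta$te_ms) {
    stop("phase images must carry echo times with te2 > te1")
  }
  out <- p1
  out$data <- wrap_phase(p2$data - p1$data)
  mask1 <- p1$meta$mask %||% array(TRUE, dim(p1$data))
  mask2 <- p2$meta$mask %||% array(TRUE, dim(p2$data))
  out$meta <- list(kind = "phase_difference",
                   dte_ms = p2$meta$te_ms - p1$meta$te_ms,
                   f0_hz = p1$meta$f0_hz, mask = mask1 & mask2)
  out
}

# local phase-gradient energy -> unwrapping quality (inverse variance style):
# voxels in smooth regions get high quality and are unwrapped first
phase_quality <- function(data, mask) {
  d <- dim(data)
  g2 <- array(0, d)
  for (axis in 1:3) {
    if (d[axis] < 2) next
    # forward wrapped differences along `axis`
    take <- function(from, to) {
      ix <- lapply(d, seq_len)
      ix[[axis]] <- from:to
      do.call(`[`, c(list(data), ix, list(drop = FALSE)))
    }
    df <- wrap_phase(take(2, d[axis]) - take(1, d[axis] - 1))
    # accumulate |grad|^2 on both neighbours of each face
    lo <- array(0, d); hi <- array(0, d)
    ixlo <- lapply(d, seq_len); ixlo[[axis]] <- seq_len(d[axis] - 1)
    ixhi <- lapply(d, seq_len); ixhi[[axis]] <- 2:d[axis]
    lo <- do.call(`[<-`, c(list(lo), ixlo, list(value = df^2)))
    hi <- do.call(`[<-`, c(list(hi), ixhi, list(value = df^2)))
    g2 <- g2 + lo + hi
  }
  q <- 1 / (1e-6 + g2)
  q[!mask] <- 0
  q
}

#' Unwrap a wrapped phase map by quality-guided region growing
#'
#' Recovers continuous phase from values known modulo 2*pi. Voxels are
#' unwrapped in order of a quality measure (inverse local phase-gradient
#' energy), growing from the highest-quality voxel of each connected mask
#' component, so noisy or fast-varying regions are visited last. The result
#' is defined up to one additive multiple of 2*pi per connected component;
#' when the mask has several components the ambiguity is flagged with a
#' warning and the component index is stored in `meta$component`.
#'
#' @param wrapped A phase [image_volume()] (values in `[-pi, pi)` on the
#'   mask). Requires the Itoh condition: true adjacent-voxel phase
#'   differences below pi in magnitude.
#' @return An [image_volume()] of unwrapped phase (NA off the mask), with
#'   the input metadata preserved.
#' @export
unwrap_phase_map <- function(wrapped) {
  mask <- wrapped$meta$mask %||% array(TRUE, dim(wrapped$data))
  q <- phase_quality(wrapped$data, mask)
  res <- .unwrap_qg(wrapped$data, mask, q, dim(wrapped$data))
  if (res$n_components > 1) {
    warn(sprintf("mask has %d disconnected components; each is unwrapped independently (2*pi offsets between components are arbitrary)",
                 res$n_components))
  }
  out <- wrapped
  out$data <- res$unwrapped
  out$data[!mask] <- NA_real_
  out$meta$component <- res$component
  out$meta$kind <- "phase_unwrapped"
  out
}

#' Convert an unwrapped phase-difference map to a ppm field map
#'
#' The field deviation in ppm is computed from the phase difference accrued
#' over the echo-time difference, referenced to the masked-mean field:
#' `ppm = (dphi - mean(dphi)) / (2*pi * f0 * dTE) * 1e6`. Homogeneity is a
#' deviation measure, so a global frequency offset does not affect the map;
#' the absolute central frequency is tracked separately in the QA reports.
#'
#' @param unwrapped_delta Unwrapped phase-difference [image_volume()]
#'   carrying `meta$dte_ms`.
#' @param f0_hz Central frequency (Hz).
#' @return An [image_volume()] of ppm deviations (NA off the mask), with
#'   `meta$f0_hz` and `meta$dte_ms` set.
#' @export
phase_to_ppm <- function(unwrapped_delta, f0_hz = NULL) {
  dte_ms <- unwrapped_delta$meta$dte_ms
  if (is.null(dte_ms) || dte_ms == 0) stop("input must carry a nonzero echo-time difference")
  f0_hz <- f0_hz %||% unwrapped_delta$meta$f0_hz
  if (is.null(f0_hz) || f0_hz <= 0) stop("f0_hz must be positive")
  mask <- unwrapped_delta$meta$mask %||% array(TRUE, dim(unwrapped_delta$data))
  dphi <- unwrapped_delta$data
  dev <- dphi - mean(dphi[mask])
  out <- unwrapped_delta
  out$data <- dev / (2 * pi * f0_hz * dte_ms * 1e-3) * 1e6
  out$data[!mask] <- NA_real_
  out$meta$kind <- "ppm"
  out$meta$f0_hz <- f0_hz
  out
}

#' Volume RMS of a ppm map over a centered spherical volume
#'
#' The homogeneity figure of merit: root-mean-square ppm deviation over all
#' masked voxels whose centers lie inside the sphere of the given diameter
#' centered at the isocenter (the DSV, diameter of spherical volume).
#'
#' @param map A ppm [image_volume()] (from [phase_to_ppm()] or a generator
#'   truth).
#' @param diameter_mm DSV diameter (mm).
#' @param slicewise If `TRUE`, additionally return per-z-slice RMS values.
#' @return The RMS in ppm (scalar), or a list with `vrms_ppm` and a
#'   `by_slice` tibble when `slicewise = TRUE`.
#' @export
dsv_rms <- function(map, diameter_mm = 310, slicewise = FALSE) {
  mask <- map$meta$mask %||% array(TRUE, dim(map$data))
  r <- vol_radius(map)
  sel <- mask & r <= diameter_mm / 2 & !is.na(map$data)
  if (!any(sel)) stop("no masked voxels inside the requested sphere")
  v <- sqrt(mean(map$data[sel]^2))
  if (!slicewise) return(v)
  ks <- seq_len(dim(map$data)[3])
  by_slice <- purrr::map_dfr(ks, function(k) {
    s <- sel[, , k]
    tibble::tibble(slice = k, n = sum(s),
                   rms_ppm = if (any(s)) sqrt(mean(map$data[, , k][s]^2)) else NA_real_)
  })
  list(vrms_ppm = v, by_slice = by_slice[by_slice$n > 0, ])
}

#' End-to-end B0 field-homogeneity analysis from two phase images
#'
#' Chains [phase_difference_map()], [unwrap_phase_map()] and
#' [phase_to_ppm()].
#'
#' @param p1,p2 Phase [image_volume()]s at the two echo times.
#' @param f0_hz Central frequency (Hz).
#' @return A ppm [image_volume()].
#' @export
b0_field_map <- function(p1, p2, f0_hz = 42587276) {
  phase_difference_map(p1, p2) |>
    unwrap_phase_map() |>
    phase_to_ppm(f0_hz = f0_hz)
}
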