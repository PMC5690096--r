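#' Parametric geometric distortion model
#'
#' Describes system-level geometric distortion (gradient nonlinearity plus
#' static-field effects) as a smooth displacement field over isocenter-centered
#' physical coordinates. Two ingredients can be combined: a pure radial term
#' `d(r) = a * r^3` directed away from the isocenter, and per-axis polynomial
#' terms up to total degree 5. The displacement at the isocenter is exactly
#' zero by construction (polynomial terms have no constant part).
#'
#' @param radial_a Coefficient of the radial cubic term in mm^-2; the
#'   displacement magnitude at radius `r` mm is `radial_a * r^3` mm, directed
#'   radially outward (inward for negative values).
#' @param poly Optional tibble/data.frame of polynomial terms with columns
#'   `axis` (1, 2 or 3: the displacement component), `px`, `py`, `pz`
#'   (non-negative integer exponents, total degree between 1 and 5) and
#'   `coef` (mm per mm^degree).
#' @return An object of class `distortion_model`.
#' @examples
#' m <- radial_cubic_model(magnitude_mm = 2, at_radius_mm = 150)
#' evaluate_distortion(m, cbind(150, 0, 0))  # 2 mm along +x
#' @export
distortion_model <- function(radial_a = 0, poly = NULL) {
  stopifnot(is.numeric(radial_a), length(radial_a) == 1)
  if (!is.null(poly)) {
    poly <- tibble::as_tibble(poly)
    stopifnot(all(c("axis", "px", "py", "pz", "coef") %in% names(poly)))
    deg <- poly$px + poly$py + poly$pz
    if (any(deg < 1) || any(deg > 5)) {
      stop("polynomial terms must have total degree between 1 and 5")
    }
    if (!all(poly$axis %in% 1:3)) stop("poly$axis must be 1, 2 or 3")
  }
  structure(list(radial_a = radial_a, poly = poly), class = "distortion_model")
}

#' @rdname distortion_model
#' @param magnitude_mm,at_radius_mm Convenience constructor for the pure
#'   radial cubic model scaled so that the displacement magnitude equals
#'   `magnitude_mm` at radius `at_radius_mm`.
#' @export
radial_cubic_model <- function(magnitude_mm, at_radius_mm) {
  distortion_model(radial_a = magnitude_mm / at_radius_mm^3)
}

#' Evaluate a distortion model at physical points
#'
#' @param model A [distortion_model()].
#' @param points An n x 3 matrix of isocenter-centered coordinates (mm).
#' @return An n x 3 matrix of displacement vectors (mm).
#' @export
evaluate_distortion <- function(model, points) {
  stopifnot(inherits(model, "distortion_model"))
  points <- matrix(as.numeric(points), ncol = 3)
  disp <- matrix(0, nrow(points), 3)
  if (model$radial_a != 0) {
    r2 <- rowSums(points^2)
    disp <- disp + model$radial_a * r2 * points  # |d| = a * r^3, radial
  }
  if (!is.null(model$poly)) {
    for (t in seq_len(nrow(model$poly))) {
      term <- model$poly[t, ]
      disp[, term$axis] <- disp[, term$axis] +
        term$coef * points[, 1]^term$px * points[, 2]^term$py * points[, 3]^term$pz
    }
  }
  disp
}

#' @export
print.distortion_model <- function(x, ...) {
  cat("<distortion_model>\n")
  cat(sprintf("  radial cubic: a = %.4g mm^-2 (|d| = %.3g mm at r = 150 mm)\n",
              x$radial_a, abs(x$radial_a) * 150^3))
  if (!is.null(x$poly)) cat(sprintf("  + %d polynomial term(s)\n", nrow(x$poly)))
  invisible(x)
}
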