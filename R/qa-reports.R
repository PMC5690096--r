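#' Build a QA metric entry
#'
#' One row of a QA report: a named metric with optional tolerance bounds and
#' the evaluated pass/fail flag. Every entry that carries a tolerance is
#' evaluated; entries without bounds get `NA` (recorded, not judged).
#'
#' @param metric Metric name.
#' @param value Measured value.
#' @param units Units string.
#' @param lower,upper Tolerance bounds (either may be `NA` for one-sided).
#' @param note Free-text note.
#' @return A one-row tibble with columns `metric`, `value`, `units`,
#'   `lower`, `upper`, `pass`, `note`.
#' @export
qa_entry <- function(metric, value, units = "", lower = NA_real_,
                     upper = NA_real_, note = "") {
  pass <- if (is.na(lower) && is.na(upper)) {
    NA
  } else {
    (is.na(lower) | value >= lower) & (is.na(upper) | value <= upper)
  }
  tibble::tibble(metric = metric, value = as.numeric(value), units = units,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 pass = pass, note = note)
}

#' Central-frequency drift check
#'
#' Day-to-day resonant-frequency stability: the drift relative to the
#' previous session must stay under the ACR daily-change allowance
#' (1.5 ppm), and the absolute frequency must remain inside the
#' manufacturer's bounds. A service event that re-centers the frequency is
#' handled by resetting `previous_hz` to the new baseline.
#'
#' @param frequency_hz Measured central frequency (Hz).
#' @param previous_hz Previous session's frequency (Hz), or the fixed
#'   baseline when trending against acceptance values.
#' @param ppm_limit Daily-change limit (ppm).
#' @param bounds_hz Manufacturer's absolute frequency window (Hz, length 2),
#'   or `NULL` to skip the absolute check.
#' @return A tibble with the drift entries: drift in Hz and ppm, the limit
#'   in Hz, and pass/fail flags.
#' @examples
#' central_frequency_check(42587276 - 42, 42587276)
#' @export
central_frequency_check <- function(frequency_hz, previous_hz,
                                    ppm_limit = 1.5,
                                    bounds_hz = c(42584000, 42591000)) {
  if (previous_hz <= 0 || frequency_hz <= 0) stop("frequencies must be positive")
  drift_hz <- frequency_hz - previous_hz
  drift_ppm <- hz_to_ppm(abs(drift_hz), previous_hz)
  limit_hz <- ppm_to_hz(ppm_limit, previous_hz)
  out <- dplyr::bind_rows(
    qa_entry("central_frequency", frequency_hz, "Hz",
             lower = if (is.null(bounds_hz)) NA_real_ else bounds_hz[1],
             upper = if (is.null(bounds_hz)) NA_real_ else bounds_hz[2],
             note = "absolute frequency within manufacturer bounds"),
    qa_entry("central_frequency_drift", abs(drift_hz), "Hz",
             upper = limit_hz,
             note = sprintf("daily change vs previous %0.0f Hz", previous_hz)),
    qa_entry("central_frequency_drift_ppm", drift_ppm, "ppm",
             upper = ppm_limit, note = "ACR daily-change allowance")
  )
  attr(out, "limit_hz") <- limit_hz
  out
}

#' Slice-thickness check from a ramp phantom image
#'
#' Measures the full width at half maximum of the ramp-band profile (taken
#' perpendicular to the band, averaged along it) by linear interpolation at
#' the half-maximum level, converts it to slice thickness via
#' `thickness = FWHM * tan(ramp_angle)`, and compares with the nominal
#' thickness.
#'
#' @param ramp_image The ramp [image_volume()] (band along x, profile
#'   along y), e.g. from [gen_ramp_volume()].
#' @param ramp_angle_deg Ramp angle (degrees).
#' @param nominal_mm Nominal slice thickness (mm).
#' @param tolerance_mm Allowed absolute deviation (mm); the ACR slice
#'   thickness criterion of +/- 0.7 mm is the default.
#' @return A tibble with the FWHM and thickness entries; when no band is
#'   found a failing entry with a diagnostic note is returned instead of an
#'   error.
#' @export
slice_thickness_check <- function(ramp_image, ramp_angle_deg = 11,
                                  nominal_mm = 5, tolerance_mm = 0.7) {
  profile <- rowMeans(colMeans(ramp_image$data))  # average over x then z
  pos <- vol_axis_coords(ramp_image, 2)
  fwhm <- profile_fwhm(pos, profile)
  if (is.na(fwhm)) {
    return(qa_entry("slice_thickness", NA_real_, "mm",
                    lower = nominal_mm - tolerance_mm,
                    upper = nominal_mm + tolerance_mm,
                    note = "ramp band not found") |>
             dplyr::mutate(pass = FALSE))
  }
  thickness <- fwhm * tan(ramp_angle_deg * pi / 180)
  dplyr::bind_rows(
    qa_entry("ramp_profile_fwhm", fwhm, "mm", note = "full width at half maximum"),
    qa_entry("slice_thickness", thickness, "mm",
             lower = nominal_mm - tolerance_mm,
             upper = nominal_mm + tolerance_mm,
             note = sprintf("FWHM x tan(%g deg) vs nominal %g mm",
                            ramp_angle_deg, nominal_mm))
  )
}

# FWHM of a 1-D profile by linear interpolation at half maximum
profile_fwhm <- function(pos, val) {
  if (max(val) - min(val) < .Machine$double.eps^0.5) return(NA_real_)
  half <- min(val) + (max(val) - min(val)) / 2
  above <- val >= half
  if (!any(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- tail(which(above), 1)
  left <- if (i1 == 1) pos[1] else {
    pos[i1 - 1] + (half - val[i1 - 1]) / (val[i1] - val[i1 - 1]) * (pos[i1] - pos[i1 - 1])
  }
  right <- if (i2 == length(val)) pos[i2] else {
    pos[i2] + (half - val[i2]) / (val[i2 + 1] - val[i2]) * (pos[i2 + 1] - pos[i2])
  }
  right - left
}

#' Laser positioning tolerance checks
#'
#' External-laser QA bookkeeping: crosshair offsets from the magnet
#' isocenter (per axis) are held to 2 mm, and individual laser motion tests
#' (e.g. a programmed 200 mm vertical move or +/-100 mm sagittal moves) are
#' held to 1 mm of the expected travel, following AAPM TG-66 practice.
#'
#' @param crosshair_offsets_mm Named numeric vector of per-axis crosshair
#'   offsets (mm), e.g. `c(x = 0.5, y = -0.3, z = 1.1)`.
#' @param motion_tests Optional tibble/data.frame with columns `laser`,
#'   `expected_mm`, `measured_mm`.
#' @param crosshair_tol_mm,motion_tol_mm Tolerances (mm).
#' @return A tibble of QA entries.
#' @export
laser_tolerance_check <- function(crosshair_offsets_mm,
                                  motion_tests = NULL,
                                  crosshair_tol_mm = 2, motion_tol_mm = 1) {
  stopifnot(all(is.finite(crosshair_offsets_mm)))
  entries <- purrr::imap_dfr(as.list(crosshair_offsets_mm), function(v, ax) {
    qa_entry(paste0("laser_crosshair_offset_", ax), abs(v), "mm",
             upper = crosshair_tol_mm, note = "crosshair offset from isocenter")
  })
  if (!is.null(motion_tests)) {
    mt <- tibble::as_tibble(motion_tests)
    entries <- dplyr::bind_rows(entries, purrr::pmap_dfr(mt, function(laser, expected_mm, measured_mm) {
      qa_entry(paste0("laser_motion_", laser),
               abs(measured_mm - expected_mm), "mm", upper = motion_tol_mm,
               note = sprintf("programmed %g mm move", expected_mm))
    }))
  }
  entries
}

#' Default QA tolerance table
#'
#' The package-wide tolerance defaults: 2 mm laser crosshair offset, 1 mm
#' individual laser motion, 1.5 ppm daily central-frequency change (ACR),
#' and 2 ppm volume-RMS field homogeneity (ACR), each listed exactly once
#' with its provenance.
#'
#' @return A tibble with `metric`, `tolerance`, `units`, `source`.
#' @export
default_tolerances <- function() {
  tibble::tribble(
    ~metric, ~tolerance, ~units, ~source,
    "laser_crosshair_offset", 2, "mm", "external laser system commissioning tolerance",
    "laser_motion", 1, "mm", "AAPM TG-66 laser motion tolerance",
    "central_frequency_drift", 1.5, "ppm", "ACR daily central-frequency change",
    "b0_homogeneity_vrms", 2, "ppm", "ACR field-homogeneity recommendation"
  )
}

#' Assemble, serialize and read QA reports
#'
#' A QA report bundles a session timestamp, a table of metric entries and
#' free-text notes, with an overall status: `"FAIL"` if any evaluated entry
#' fails, `"PASS"` if all evaluated entries pass, `"NA"` when nothing was
#' evaluated. JSON serialization round-trips to an identical report;
#' [qa_report_csv()] exports the metric table.
#'
#' @param entries Tibble of entries from [qa_entry()] and friends.
#' @param session Session timestamp string (ISO 8601); defaults to now.
#' @param notes Free-text notes.
#' @return An object of class `qa_report`.
#' @export
qa_report <- function(entries, session = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      notes = "") {
  entries <- tibble::as_tibble(entries)
  for (a in setdiff(names(attributes(entries)),
                    c("names", "row.names", "class"))) {
    attr(entries, a) <- NULL
  }
  status <- if (!nrow(entries) || all(is.na(entries$pass))) {
    "NA"
  } else if (any(!entries$pass, na.rm = TRUE)) "FAIL" else "PASS"
  structure(list(session = session, entries = entries, notes = notes,
                 status = status),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s  overall: %s\n", x$session, x$status))
  print(x$entries, n = Inf)
  invisible(x)
}

#' @rdname qa_report
#' @param report A `qa_report`.
#' @param path Output path.
#' @export
write_qa_report <- function(report, path) {
  jsonlite::write_json(
    list(session = report$session, notes = report$notes,
         status = report$status, entries = report$entries),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname qa_report
#' @export
read_qa_report <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed QA report file '", path, "': ",
                         conditionMessage(e))
                  })
  if (!all(c("session", "entries") %in% names(obj))) {
    stop("malformed QA report file '", path, "': missing session/entries fields")
  }
  entries <- tibble::as_tibble(obj$entries)
  if (nrow(entries)) {
    entries$lower <- as.numeric(entries$lower)
    entries$upper <- as.numeric(entries$upper)
    entries$pass <- as.logical(entries$pass)
  } else {
    entries <- qa_entry("x", 0)[0, ]
  }
  qa_report(entries, session = obj$session, notes = obj$notes %||% "")
}

#' @rdname qa_report
#' @export
qa_report_csv <- function(report, path) {
  utils::write.csv(report$entries, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.qa_report <- function(x, ...) x$entries

#' @export
glance.qa_report <- function(x, ...) {
  tibble::tibble(session = x$session, status = x$status,
                 n_entries = nrow(x$entries),
                 n_fail = sum(!x$entries$pass, na.rm = TRUE))
}

#' Margin plot of a QA report
#'
#' Shows each evaluated entry's value against its tolerance band.
#'
#' @param object A `qa_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qa_report <- function(object, ...) {
  df <- dplyr::filter(object$entries, !is.na(.data$pass))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$metric, colour = .data$pass)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "value", y = NULL, colour = "pass")
}
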