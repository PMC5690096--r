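# shared small fixtures, built in code at test time

# compact capsule lattice (5 x 5 x 5 markers) for fast detection tests
small_lattice <- function(extent = 150) {
  lattice_spec(extent_mm = extent, fov_semiaxes_mm = NULL)
}

small_pair <- function(model = distortion_model(), ...) {
  gen_grid_phantom_pair(small_lattice(), model, spacing = 2, ...)
}

# analytic shell statistics from a generator truth table
truth_shell_stats <- function(truth, edges) {
  r <- sqrt(truth$x^2 + truth$y^2 + truth$z^2)
  purrr::map_dfr(seq_len(length(edges) - 1), function(q) {
    d <- truth$d_mag[r >= edges[q] & r < edges[q + 1]]
    tibble::tibble(r_min = edges[q], r_max = edges[q + 1],
                   n = length(d),
                   mean_mm = if (length(d)) mean(d) else NA_real_,
                   max_mm = if (length(d)) max(d) else NA_real_)
  })
}

# parabolic field peak (ppm at the sphere surface) whose mean-removed RMS
# over a ball of radius R equals the requested value; closed form from
# <r^2> = 3R^2/5 and <r^4> = 3R^4/7 over the ball
parabola_peak_for_rms <- function(rms_ppm) rms_ppm / sqrt(12 / 175)
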