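# Shared fixtures: analytic ellipse masks and small phantom specs.

# Rasterized filled ellipse (semi-axes in pixels, rotation in degrees,
# counter-clockwise from +x toward +y) as a cross_section_mask.
make_ellipse_mask <- function(a_px, b_px, theta_deg = 0, pixel_spacing = 30,
                              pad = 4) {
  half <- ceiling(max(a_px, b_px)) + pad
  n <- 2L * half + 1L
  cx <- cy <- half + 1
  th <- theta_deg * pi / 180
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  ys <- matrix(seq_len(n), n, n) - cy
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  cross_section_mask((u / a_px)^2 + (v / b_px)^2 <= 1, pixel_spacing)
}

# Small phantoms used across morphometry tests (kept short to stay fast).
small_undulated_spec <- function(voxel_size_um = 30,
                                 undulation_wavelength_mm = 3, ...) {
  whisker_spec("undulated", length_mm = 9,
               undulation_wavelength_mm = undulation_wavelength_mm,
               voxel_size_um = voxel_size_um, ...)
}

small_smooth_spec <- function(voxel_size_um = 30, ...) {
  whisker_spec("smooth", length_mm = 9, voxel_size_um = voxel_size_um, ...)
}

circular_spec <- function(...) {
  whisker_spec("smooth", length_mm = 6, base_eccentricity = 0,
               tip_eccentricity = 0, taper_exponent = 0, theta_profile = 0,
               ...)
}

# Balanced random study table for ANOVA oracle comparisons.
random_study_table <- function(n_per_species, angles = c(0, 45, 90),
                               effect = 0) {
  rows <- list()
  for (g in seq_along(n_per_species)) {
    sp <- LETTERS[g]
    for (i in seq_len(n_per_species[g])) {
      subj_eff <- stats::rnorm(1, 0, 1)
      for (j in seq_along(angles)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%02d", sp, i), species = sp,
          angle_deg = angles[j],
          peak_freq_hz = 100 + effect * j + subj_eff + stats::rnorm(1),
          peak_vel_m_s = stats::rnorm(1), length_cm = stats::rnorm(1, 7.7, 0.5))
      }
    }
  }
  do.call(rbind, rows)
}
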