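#' Design of a multi-subject species-by-angle study
#'
#' Describes the repeated-measures design to simulate: per-species subject
#' counts, angle-of-attack levels, and per species-by-angle cell means and
#' standard errors for peak vibration frequency and peak velocity. Every
#' subject is measured at every angle; a shared per-subject random effect
#' induces the within-subject correlation of a repeated-measures design.
#'
#' The cell SE is interpreted as the standard error of the cell mean at the
#' reference subject count it was reported for (`se_reference_n`, by default
#' the design's own counts), so the implied between-subject SD within a cell
#' is `SE * sqrt(n_ref)` and stays fixed when the simulated cohort is scaled
#' up. That SD is split into the shared subject effect
#' (`subject_sd`) and an independent residual `sqrt(SD^2 - subject_sd^2)`
#' (floored at 0). Values are Gaussian and not truncated, so generated cell
#' means converge exactly to the design means as counts grow.
#'
#' @param cells data.frame with columns `species`, `angle_deg`,
#'   `freq_mean`, `freq_se`, `vel_mean`, `vel_se` — one row per
#'   species-by-angle cell, with every species appearing at every angle.
#' @param n_subjects named integer vector, subjects per species (>= 2).
#' @param length_mean_cm,length_sd_cm named numeric vectors per species:
#'   whisker sample lengths.
#' @param se_reference_n named integer vector per species: the subject
#'   count at which the cell SEs were reported (default `n_subjects`).
#' @param subject_sd named list with elements `freq` and `vel`: the
#'   between-subject SD shared across angles, or `"auto"` (half the
#'   smallest implied cell SD per variable, so no cell's residual variance
#'   collapses to zero).
#' @param seed integer seed.
#' @return An object of class `study_design`.
#' @seealso [default_study_design()], [generate_study_table()]
#' @export
study_design <- function(cells, n_subjects, length_mean_cm, length_sd_cm,
                         se_reference_n = n_subjects,
                         subject_sd = "auto", seed = 1L) {
  need <- c("species", "angle_deg", "freq_mean", "freq_se", "vel_mean", "vel_se")
  stopifnot(is.data.frame(cells), all(need %in% names(cells)))
  species <- unique(cells$species)
  angles <- sort(unique(cells$angle_deg))
  stopifnot(all(angles %in% c(0, 45, 90)), length(angles) >= 2,
            nrow(cells) == length(species) * length(angles),
            all(names(n_subjects) %in% species), all(n_subjects >= 2),
            all(cells$freq_se > 0 | cells$freq_se == 0),
            all(cells$vel_se >= 0))
  stopifnot(all(names(se_reference_n) %in% species), all(se_reference_n >= 1))
  if (identical(subject_sd, "auto")) {
    imp <- function(se) se * sqrt(se_reference_n[cells$species])
    subject_sd <- list(freq = 0.5 * min(imp(cells$freq_se)),
                       vel = 0.5 * min(imp(cells$vel_se)))
  }
  stopifnot(is.list(subject_sd), all(c("freq", "vel") %in% names(subject_sd)))
  structure(list(cells = cells, species = species, angles = angles,
                 n_subjects = n_subjects, se_reference_n = se_reference_n,
                 length_mean_cm = length_mean_cm,
                 length_sd_cm = length_sd_cm,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "study_design")
}

#' Default three-species flume study design
#'
#' The packaged study conditions: California sea lion (smooth vibrissae),
#' northern elephant seal and harbor seal (undulated vibrissae), measured
#' at 0, 45 and 90 degrees angle of attack, with the retained
#' repeated-measures sample sizes 8/8/6 and the published per-cell means
#' and standard errors for measured peak frequency (Hz) and peak velocity
#' (m/s).
#'
#' @param seed integer seed.
#' @param n_subjects optionally override subject counts (named vector with
#'   entries for `CSL`, `ES`, `HS`).
#' @param subject_sd optionally override the shared subject-effect SDs.
#' @return A [study_design()].
#' @export
default_study_design <- function(seed = 1L,
                                 n_subjects = c(CSL = 8L, ES = 8L, HS = 6L),
                                 subject_sd = "auto") {
  cells <- data.frame(
    species = rep(c("CSL", "ES", "HS"), each = 3),
    angle_deg = rep(c(0, 45, 90), times = 3),
    freq_mean = c(204.4, 156.7, 112.5,
                  151.3, 140.0, 121.3,
                  202.8, 157.2, 95.0),
    freq_se = c(9.4, 13.4, 4.6,
                5.9, 7.3, 5.2,
                7.3, 17.6, 4.3),
    vel_mean = c(0.0087, 0.0426, 0.1099,
                 0.0029, 0.0559, 0.1745,
                 0.0069, 0.0484, 0.1192),
    vel_se = c(0.0029, 0.0142, 0.0172,
               0.0010, 0.0280, 0.0226,
               0.0038, 0.0167, 0.0175))
  study_design(cells, n_subjects = n_subjects,
               length_mean_cm = c(CSL = 7.70, ES = 8.19, HS = 7.35),
               length_sd_cm = c(CSL = 0.4, ES = 0.5, HS = 0.4),
               se_reference_n = c(CSL = 8L, ES = 8L, HS = 6L),
               subject_sd = subject_sd, seed = seed)
}

#' Generate a per-subject study table from a design
#'
#' Draws one row per subject-by-angle: value = cell mean + shared subject
#' effect + independent residual (see [study_design()] for the variance
#' split). Subject whisker lengths are drawn once per subject from the
#' species length distribution.
#'
#' @param design a [study_design()].
#' @return A data.frame (class `study_table`) with columns `subject_id`,
#'   `species`, `angle_deg`, `peak_freq_hz`, `peak_vel_m_s`, `length_cm`.
#' @export
generate_study_table <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::with_seed(design$seed, {
    rows <- list()
    for (sp in design$species) {
      n <- design$n_subjects[[sp]]
      eff_f <- stats::rnorm(n, 0, design$subject_sd$freq)
      eff_v <- stats::rnorm(n, 0, design$subject_sd$vel)
      len <- stats::rnorm(n, design$length_mean_cm[[sp]],
                          design$length_sd_cm[[sp]])
      n_ref <- design$se_reference_n[[sp]]
      for (j in seq_along(design$angles)) {
        cell <- design$cells[design$cells$species == sp &
                             design$cells$angle_deg == design$angles[j], ]
        sd_f <- sqrt(max(0, (cell$freq_se * sqrt(n_ref))^2 -
                            design$subject_sd$freq^2))
        sd_v <- sqrt(max(0, (cell$vel_se * sqrt(n_ref))^2 -
                            design$subject_sd$vel^2))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s_%02d", sp, seq_len(n)),
          species = sp,
          angle_deg = design$angles[j],
          peak_freq_hz = cell$freq_mean + eff_f + stats::rnorm(n, 0, sd_f),
          peak_vel_m_s = cell$vel_mean + eff_v + stats::rnorm(n, 0, sd_v),
          length_cm = len)
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$subject_id, out$angle_deg), ]
  rownames(out) <- NULL
  class(out) <- c("study_table", class(out))
  out
}
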