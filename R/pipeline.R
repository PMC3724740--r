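#' Configuration for an end-to-end synthetic flume study
#'
#' Bundles everything [run_study()] needs: flow conditions, one whisker
#' spec per species (smooth for the sea lion archetype, undulated for the
#' true-seal archetypes), the multi-subject study design, recording
#' parameters, and stage toggles.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param flow a [flow_conditions()].
#' @param whisker_specs named list of [whisker_spec()] objects, one per
#'   species code in the design.
#' @param design a [study_design()].
#' @param tone_source `"design"` (tone frequency/amplitude per
#'   subject-by-angle drawn from the study design cells — the published
#'   group structure) or `"theory"` (tone frequency set to the shedding
#'   prediction for that species and angle, 45 degrees taking the midpoint
#'   of the 0/90 predictions — the closed-loop configuration whose
#'   measured-vs-theoretical percent difference should be ~0).
#' @param snap_tones_to_bins snap tone frequencies to the spectral bin grid
#'   (default TRUE) so peak recovery is exact rather than scalloped.
#' @param nfft,noise_floor,sting_amplitude recording/analysis parameters.
#' @param exclude_band frequency band excluded from peak picking; default
#'   0-50 Hz, rejecting the sting-mount artifact band.
#' @param centroid `"half_arc"` (reference section at half the arc length,
#'   default) or `"volumetric"` (area-weighted mean arc position).
#' @param stages named logical list enabling `morph`, `spectra`, `theory`,
#'   `stats`.
#' @param mismatch_hz optional frequency offset added to every tone — a
#'   knob to inject a known measured-vs-theoretical discrepancy.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         flow = flow_conditions(),
                         whisker_specs = list(
                           CSL = whisker_spec("smooth"),
                           ES = whisker_spec("undulated"),
                           HS = whisker_spec("undulated",
                                             undulation_wavelength_mm = 2.2)),
                         design = default_study_design(seed = seed),
                         tone_source = c("design", "theory"),
                         snap_tones_to_bins = TRUE,
                         nfft = 240,
                         noise_floor = 2e-4,
                         sting_amplitude = 0.005,
                         exclude_band = c(0, 50),
                         centroid = c("half_arc", "volumetric"),
                         stages = list(morph = TRUE, spectra = TRUE,
                                       theory = TRUE, stats = TRUE),
                         mismatch_hz = 0) {
  tone_source <- match.arg(tone_source)
  centroid <- match.arg(centroid)
  stopifnot(inherits(flow, "flow_conditions"),
            inherits(design, "study_design"),
            all(design$species %in% names(whisker_specs)),
            all(vapply(whisker_specs, inherits, logical(1), "whisker_spec")))
  structure(list(seed = as.integer(seed), flow = flow,
                 whisker_specs = whisker_specs, design = design,
                 tone_source = tone_source,
                 snap_tones_to_bins = snap_tones_to_bins,
                 nfft = nfft, noise_floor = noise_floor,
                 sting_amplitude = sting_amplitude,
                 exclude_band = exclude_band, centroid = centroid,
                 stages = stages, mismatch_hz = mismatch_hz),
            class = "study_config")
}

# Short deterministic hash of a config for the run log.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Shedding-frequency predictions per phantom at 0 and 90 degrees
#'
#' For each species phantom, takes the reference cross-section (half arc
#' length by default), reads the stream-wise diameter facing the flow at
#' each orientation — the minimum caliper width at 0 degrees (thin edge
#' into the flow), the maximum at 90 degrees (broad face into the flow) —
#' and predicts the vortex-shedding frequency. For undulated phantoms the
#' crest and trough nearest the reference section bound the diameter, so
#' the prediction is an interval (`f_low`, `f_high`) with its midpoint as
#' the group-comparable scalar; for smooth phantoms the interval collapses.
#' The 45 degree orientation is never predicted (the profile facing the
#' flow is an angled plane there).
#'
#' @param profiles named list of `shaft_profile` data.frames (one per
#'   species, from [profile_along_shaft()] or a phantom's `truth`).
#' @param flow a [flow_conditions()].
#' @param centroid `"half_arc"` or `"volumetric"`.
#' @return data.frame: `species`, `angle_deg`, `d_max_m`, `d_min_m`,
#'   `f_low`, `f_high`, `f_mid`, `Re_mid`, `regime`.
#' @export
angle_sweep_prediction <- function(profiles, flow,
                                   centroid = c("half_arc", "volumetric")) {
  centroid <- match.arg(centroid)
  out <- list()
  for (sp in names(profiles)) {
    prof <- profiles[[sp]]
    n <- nrow(prof)
    c_idx <- if (centroid == "half_arc") {
      which.min(abs(prof$arc_mm - max(prof$arc_mm) / 2))
    } else {
      which.min(abs(prof$arc_mm -
                    sum(prof$arc_mm * prof$area_mm2) / sum(prof$area_mm2)))
    }
    crests <- attr(prof, "crest_indices")
    troughs <- attr(prof, "trough_indices")
    ref_idx <- if (length(crests) >= 1 && length(troughs) >= 1) {
      c(crests[which.min(abs(crests - c_idx))],
        troughs[which.min(abs(troughs - c_idx))])
    } else c_idx
    for (angle in c(0, 90)) {
      d_mm <- if (angle == 0) prof$feret_min_mm[ref_idx]
              else prof$feret_max_mm[ref_idx]
      rng <- tryCatch(
        undulated_frequency_range(flow, max(d_mm) / 1000, min(d_mm) / 1000),
        error = function(e) stop(sprintf("phantom %s at %d deg: %s", sp,
                                         angle, conditionMessage(e)),
                                 call. = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, angle_deg = angle,
        d_max_m = max(d_mm) / 1000, d_min_m = min(d_mm) / 1000,
        f_low = rng$f_low, f_high = rng$f_high, f_mid = rng$f_mid,
        Re_mid = mean(rng$detail$Re), regime = rng$detail$regime[1])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run an end-to-end synthetic flume study
#'
#' Generates one whisker phantom per species and profiles it, predicts
#' shedding frequencies at 0 and 90 degrees, synthesizes a vibrometer
#' recording for every subject-by-angle condition, extracts the spectral
#' peaks, and runs the group statistics on the measured peaks — the full
#' study pipeline on data with known ground truth. Deterministic under a
#' fixed config seed. When `out_dir` is given, every enabled stage writes
#' its CSV artifact there plus a `run_log.txt` recording seeds and the
#' config hash.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A list of class `study_report`: `profiles`, `predictions`,
#'   `measured` (study table of spectral peaks), `summaries` (per-variable
#'   group summaries; the frequency summary carries theoretical
#'   frequencies and mean percent differences at 0/90), `anova`, `tukey`,
#'   `regressions`, `log`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  stages <- config$stages
  design <- config$design
  report <- list()

  # -- morphometry stage: phantom per species -------------------------------
  profiles <- list()
  for (sp in design$species) {
    ph <- generate_phantom(config$whisker_specs[[sp]])
    if (isTRUE(stages$morph)) {
      profiles[[sp]] <- profile_along_shaft(ph$volume)
    } else {
      tr <- ph$truth
      ext <- detect_crests_troughs(tr$feret_max_mm)
      attr(tr, "crest_indices") <- ext$crest_indices
      attr(tr, "trough_indices") <- ext$trough_indices
      profiles[[sp]] <- tr
    }
  }
  report$profiles <- profiles

  # -- theory stage ---------------------------------------------------------
  pred <- NULL
  if (isTRUE(stages$theory)) {
    pred <- angle_sweep_prediction(profiles, config$flow, config$centroid)
    report$predictions <- pred
  }

  # -- per-subject true values ---------------------------------------------
  truth_tab <- generate_study_table(design)
  bin_hz <- 1200 / config$nfft
  tone_of <- function(sp, angle, design_freq) {
    f <- if (config$tone_source == "theory") {
      if (is.null(pred)) stop("tone_source 'theory' needs the theory stage",
                              call. = FALSE)
      p <- pred[pred$species == sp, ]
      if (angle == 45) mean(p$f_mid) else p$f_mid[p$angle_deg == angle]
    } else design_freq
    f <- f + config$mismatch_hz
    if (config$snap_tones_to_bins) f <- round(f / bin_hz) * bin_hz
    # whisker tones live above the sting band by construction; keep rare
    # tail draws clear of the exclusion band and of Nyquist
    lo <- if (is.null(config$exclude_band)) bin_hz else
      config$exclude_band[2] + bin_hz
    min(max(f, lo), 600 - bin_hz)
  }

  # -- recording + spectra stage -------------------------------------------
  measured <- truth_tab
  if (isTRUE(stages$spectra)) {
    pk_f <- pk_v <- n_seg <- numeric(nrow(truth_tab))
    for (i in seq_len(nrow(truth_tab))) {
      row <- truth_tab[i, ]
      spec <- signal_spec(
        tone_frequency = tone_of(row$species, row$angle_deg, row$peak_freq_hz),
        tone_amplitude = max(row$peak_vel_m_s, 1e-4),
        noise_floor = config$noise_floor,
        sting_amplitude = config$sting_amplitude,
        seed = (config$seed * 1000L + i) %% .Machine$integer.max)
      rec <- generate_recording(spec, angle_deg = row$angle_deg)
      qf <- segment_quality_filter(rec, nfft = config$nfft)
      spctr <- averaged_fft(rec, nfft = config$nfft, segments = qf$usable)
      pk <- peak_pick(spctr, exclude_band = config$exclude_band)
      pk_f[i] <- pk$peak_frequency
      pk_v[i] <- pk$peak_velocity
      n_seg[i] <- spctr$n_segments_averaged
    }
    measured$peak_freq_hz <- pk_f
    measured$peak_vel_m_s <- pk_v
    measured$n_segments <- n_seg
  }
  report$measured <- measured

  # -- stats stage ----------------------------------------------------------
  complete <- enforce_complete_cases(measured)
  summaries <- list(freq = summarize_groups(complete, "peak_freq_hz"),
                    vel = summarize_groups(complete, "peak_vel_m_s"))
  if (!is.null(pred)) {
    sf <- summaries$freq
    sf$theoretical_f_hz <- NA_real_
    sf$pct_difference <- NA_real_
    for (r in seq_len(nrow(sf))) {
      p <- pred[pred$species == sf$species[r] &
                pred$angle_deg == sf$angle_deg[r], ]
      if (nrow(p) == 1L) {
        sf$theoretical_f_hz[r] <- p$f_mid
        sub <- complete[complete$species == sf$species[r] &
                        complete$angle_deg == sf$angle_deg[r], ]
        sf$pct_difference[r] <-
          mean(percent_difference(sub$peak_freq_hz, p$f_mid))
      }
    }
    summaries$freq <- sf
  }
  report$summaries <- summaries
  if (isTRUE(stages$stats)) {
    report$anova <- list(freq = mixed_anova(complete, "peak_freq_hz"),
                         vel = mixed_anova(complete, "peak_vel_m_s"))
    report$tukey <- list(
      freq = tukey_within_species(complete, "peak_freq_hz",
                                  report$anova$freq),
      vel = tukey_within_species(complete, "peak_vel_m_s",
                                 report$anova$vel))
    report$regressions <- list(
      freq = length_regression(complete, "peak_freq_hz"),
      vel = length_regression(complete, "peak_vel_m_s"))
  }

  report$log <- c(
    sprintf("config_hash: %s", .config_hash(config)),
    sprintf("seed: %d", config$seed),
    sprintf("tone_source: %s", config$tone_source),
    sprintf("stages: %s",
            paste(names(stages)[unlist(stages)], collapse = ",")),
    sprintf("subjects: %s",
            paste(sprintf("%s=%d", names(design$n_subjects),
                          design$n_subjects), collapse = " ")))

  if (!is.null(out_dir)) .write_report(report, out_dir, stages)
  class(report) <- "study_report"
  report
}

.write_report <- function(report, out_dir, stages) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) utils::write.csv(d, file.path(out_dir, name),
                                          row.names = FALSE)
  for (sp in names(report$profiles)) {
    w(report$profiles[[sp]], sprintf("morphometry_%s.csv", sp))
  }
  if (!is.null(report$predictions)) w(report$predictions, "predictions.csv")
  write_study_table_csv(report$measured,
                        file.path(out_dir, "measured_table.csv"))
  w(report$summaries$freq, "group_summary_freq.csv")
  w(report$summaries$vel, "group_summary_vel.csv")
  if (!is.null(report$anova)) {
    w(report$anova$freq, "anova_freq.csv")
    w(report$anova$vel, "anova_vel.csv")
    w(report$tukey$freq, "tukey_freq.csv")
    w(report$tukey$vel, "tukey_vel.csv")
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  species profiled: %s\n",
              paste(names(x$profiles), collapse = ", ")))
  if (!is.null(x$anova)) {
    cat(sprintf("  ANOVA angle effect: freq p = %.3g, vel p = %.3g\n",
                x$anova$freq$p[1], x$anova$vel$p[1]))
  }
  invisible(x)
}
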