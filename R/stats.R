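#' Drop subjects with missing angle measurements
#'
#' A repeated-measures analysis needs every retained subject measured at
#' every angle; subjects with dropped values (e.g. poor vibrometer signal
#' at 90 degrees) are removed wholesale. The removal log is attached as the
#' `removed_subjects` attribute.
#'
#' @param table a study table data.frame (`subject_id`, `species`,
#'   `angle_deg`, measurement columns).
#' @param angles the required angle levels; default the union observed.
#' @return The complete-case table; errors if fewer than 2 subjects per
#'   species remain.
#' @export
enforce_complete_cases <- function(table, angles = sort(unique(table$angle_deg))) {
  stopifnot(all(c("subject_id", "species", "angle_deg") %in% names(table)))
  ok <- vapply(split(table$angle_deg, table$subject_id),
               function(a) all(angles %in% a), logical(1))
  removed <- names(ok)[!ok]
  out <- table[table$subject_id %in% names(ok)[ok] &
               table$angle_deg %in% angles, , drop = FALSE]
  counts <- table(unique(out[, c("subject_id", "species")])$species)
  if (length(counts) == 0L || any(counts < 2)) {
    stop("insufficient data: fewer than 2 complete subjects in some species",
         call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "removed_subjects") <- removed
  out
}

# Core mixed-design decomposition on a complete, crossed layout.
# y: numeric; subject, species, angle: factors (subject nested in species).
.mixed_anova_core <- function(y, subject, species, angle) {
  N <- length(y)
  a <- nlevels(angle)
  n_subj <- nlevels(subject)
  grand <- mean(y)
  subj_mean <- tapply(y, subject, mean)
  subj_species <- species[match(levels(subject), subject)]
  spec_mean <- tapply(subj_mean, subj_species, mean)  # equal subject weight
  n_g <- table(subj_species)
  angle_mean <- tapply(y, angle, mean)
  cell_mean <- tapply(y, list(species, angle), mean)

  ss_total <- sum((y - grand)^2)
  ss_between <- a * sum((subj_mean - grand)^2)
  ss_species <- a * sum(n_g * (spec_mean - grand)^2)
  ss_subjects <- ss_between - ss_species
  ss_angle <- n_subj * sum((angle_mean - grand)^2)
  ss_cells <- 0
  for (g in rownames(cell_mean)) {
    ss_cells <- ss_cells + n_g[[g]] * sum((cell_mean[g, ] - grand)^2)
  }
  # differences of sums of squares; clamp roundoff-negative zeros
  ss_inter <- max(0, ss_cells - ss_species - ss_angle)
  ss_within <- ss_total - ss_between
  ss_resid <- max(0, ss_within - ss_angle - ss_inter)

  df_angle <- a - 1L
  df_species <- nlevels(droplevels(subj_species)) - 1L
  df_inter <- df_angle * df_species
  df_subjects <- n_subj - (df_species + 1L)
  df_resid <- df_angle * df_subjects

  ms <- c(ss_angle, ss_species, ss_inter, ss_subjects, ss_resid) /
    c(df_angle, df_species, df_inter, df_subjects, df_resid)
  f <- c(ms[1] / ms[5], ms[2] / ms[4], ms[3] / ms[5], ms[4] / ms[5])
  df2 <- c(df_resid, df_subjects, df_resid, df_resid)
  df1 <- c(df_angle, df_species, df_inter, df_subjects)
  f[df1 == 0] <- NA  # e.g. single-species tables have no species term
  p <- rep(NA_real_, 4L)
  ok <- df1 > 0 & is.finite(f)
  p[ok] <- stats::pf(f[ok], df1[ok], df2[ok], lower.tail = FALSE)
  data.frame(
    term = c("angle", "species", "interaction", "subjects", "residual"),
    SS = c(ss_angle, ss_species, ss_inter, ss_subjects, ss_resid),
    DF = c(df_angle, df_species, df_inter, df_subjects, df_resid),
    MS = ms,
    F = c(f, NA),
    DFn = c(df1, NA), DFd = c(df2, NA),
    p = c(p, NA),
    stringsAsFactors = FALSE)
}

#' Mixed-design two-factor repeated-measures ANOVA
#'
#' Species is the between-subject factor, angle of attack the
#' within-subject factor. The between-subject sum of squares splits into a
#' species effect (computed from subject means, weighted by group size)
#' and subjects-within-species; the within-subject sum of squares splits
#' into angle, species-by-angle interaction, and the angle-by-subject
#' residual. Species is tested against the subjects-within-species mean
#' square; angle and the interaction (and the subjects term itself) are
#' tested against the residual — the standard mixed-design convention. No
#' sphericity correction is applied.
#'
#' @param table a complete-case study table (see
#'   [enforce_complete_cases()]).
#' @param dv name of the dependent-variable column, e.g. `"peak_freq_hz"`.
#' @return A data.frame of class `anova_table` with columns `term`, `SS`,
#'   `DF`, `MS`, `F`, `DFn`, `DFd`, `p`.
#' @export
mixed_anova <- function(table, dv) {
  stopifnot(dv %in% names(table))
  subject <- factor(table$subject_id)
  angle <- factor(table$angle_deg)
  species <- factor(table$species)
  counts <- table(table$subject_id, table$angle_deg)
  if (any(counts != 1L)) {
    stop(paste("unbalanced within-subject data: every subject needs exactly",
               "one row per angle (run enforce_complete_cases first)"),
         call. = FALSE)
  }
  out <- .mixed_anova_core(table[[dv]], subject, species, angle)
  attr(out, "dv") <- dv
  class(out) <- c("anova_table", class(out))
  out
}

#' Tukey post-hoc comparisons of angles within each species
#'
#' For every species and every ordered angle pair, the mean difference
#' (first minus second angle) and a Tukey-adjusted p-value from the
#' studentized range distribution, using the pooled within-subject
#' residual mean square of the fitted mixed ANOVA, its degrees of freedom,
#' the number of angle levels as the number of means, and that species'
#' subject count.
#'
#' @param table the complete-case study table the ANOVA was fitted on.
#' @param dv dependent-variable column name.
#' @param anova the matching [mixed_anova()] result.
#' @return data.frame of class `tukey_result`: `species`, `comparison`,
#'   `mean_diff`, `q`, `p_adj`.
#' @export
tukey_within_species <- function(table, dv, anova) {
  stopifnot(inherits(anova, "anova_table"), identical(attr(anova, "dv"), dv))
  ms_resid <- anova$MS[anova$term == "residual"]
  df_resid <- anova$DF[anova$term == "residual"]
  angles <- sort(unique(table$angle_deg))
  k <- length(angles)
  out <- list()
  for (sp in unique(table$species)) {
    sub <- table[table$species == sp, ]
    n_g <- length(unique(sub$subject_id))
    cm <- tapply(sub[[dv]], factor(sub$angle_deg, levels = angles), mean)
    if (anyNA(cm)) stop(sprintf("missing angle cell for species %s", sp),
                        call. = FALSE)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      diff <- cm[[i]] - cm[[j]]
      se <- sqrt(ms_resid / n_g)
      q <- if (diff == 0) 0 else if (se == 0) Inf else abs(diff) / se
      out[[length(out) + 1L]] <- data.frame(
        species = sp,
        comparison = sprintf("%g vs %g", angles[i], angles[j]),
        mean_diff = diff, q = q,
        p_adj = stats::ptukey(q, nmeans = k, df = df_resid,
                              lower.tail = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tukey_result", class(res))
  res
}

#' Regression of a measurement on whisker length
#'
#' Ordinary least squares of the dependent variable on sample length (cm),
#' quantifying how much of the between-subject variation is attributable
#' to length.
#'
#' @param table study table with a `length_cm` column.
#' @param dv dependent-variable column name.
#' @return List with `slope` (dv units per cm), `intercept`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
length_regression <- function(table, dv) {
  stopifnot(dv %in% names(table), "length_cm" %in% names(table))
  if (length(unique(table$length_cm)) < 3L) {
    stop("need at least 3 distinct length values", call. = FALSE)
  }
  if (stats::var(table$length_cm) == 0) {
    stop("zero variance in length", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate("length_cm", dv), data = table)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = stats::nobs(fit), fit = fit)
}

#' Per-cell group summaries
#'
#' Mean, standard error (SD/sqrt(n)), range and count per species-by-angle
#' cell. Single-observation cells report SE 0 with `se_flag` set.
#'
#' @param table study table.
#' @param dv dependent-variable column name.
#' @return data.frame: `species`, `angle_deg`, `n`, `mean`, `se`, `min`,
#'   `max`, `se_flag`.
#' @export
summarize_groups <- function(table, dv) {
  stopifnot(dv %in% names(table))
  key <- interaction(table$species, table$angle_deg, drop = TRUE)
  out <- do.call(rbind, lapply(split(table, key), function(d) {
    v <- d[[dv]]
    data.frame(species = d$species[1], angle_deg = d$angle_deg[1],
               n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               min = min(v), max = max(v),
               se_flag = length(v) == 1L)
  }))
  out <- out[order(out$species, out$angle_deg), ]
  rownames(out) <- NULL
  out
}
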