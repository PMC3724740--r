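#' Cross-section mask of a whisker slice
#'
#' A cleaned binary cross-section: exactly one foreground connected
#' component, holes filled. Rows index the y (out-of-slide) direction and
#' columns the x (slide-plane horizontal) direction; the principal-axis
#' angle theta is measured from +x toward +y.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @param pixel_spacing pixel pitch in micrometres.
#' @param slice_index integer slice position in the source stack.
#' @param arc_position arc-length position in mm (optional).
#' @return An object of class `cross_section_mask`.
#' @export
cross_section_mask <- function(mask, pixel_spacing, slice_index = NA_integer_,
                               arc_position = NA_real_) {
  stopifnot(is.matrix(mask), pixel_spacing > 0)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  structure(list(mask = mask, pixel_spacing = pixel_spacing,
                 slice_index = as.integer(slice_index),
                 arc_position = arc_position),
            class = "cross_section_mask")
}

#' Segment one slice of a whisker volume
#'
#' Thresholds the slice (Otsu by default, or a fixed value), keeps the
#' largest connected component, and fills interior holes — the standard
#' cleanup before cross-sectional morphometry of a CT slice.
#'
#' @param volume 3-D numeric array `[y, x, slice]`, e.g. from
#'   [generate_phantom()] or [read_volume_tiff()].
#' @param slice_index which slice to segment.
#' @param threshold_policy `"otsu"` or `"fixed"`.
#' @param threshold threshold value when `threshold_policy = "fixed"`.
#' @param pixel_spacing pixel pitch in micrometres; defaults to the
#'   `voxel_size_um` attribute of `volume` if present.
#' @param ambiguity_ratio a second component larger than this fraction of
#'   the largest one raises an ambiguity error (default 0.5).
#' @return A [cross_section_mask()].
#' @export
segment_slice <- function(volume, slice_index,
                          threshold_policy = c("otsu", "fixed"),
                          threshold = 0.5,
                          pixel_spacing = attr(volume, "voxel_size_um"),
                          ambiguity_ratio = 0.5) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(length(dim(volume)) == 3L,
            slice_index >= 1L, slice_index <= dim(volume)[3])
  if (is.null(pixel_spacing)) {
    stop("pixel_spacing not given and volume has no voxel_size_um attribute",
         call. = FALSE)
  }
  sl <- volume[, , slice_index]
  rng <- range(sl)
  thr <- if (threshold_policy == "otsu") {
    if (rng[2] <= rng[1]) rng[2] + 1  # constant slice: nothing above
    else EBImage::otsu(EBImage::Image((sl - rng[1]) / (rng[2] - rng[1]))) *
           (rng[2] - rng[1]) + rng[1]
  } else threshold
  fg <- sl > thr
  if (!any(fg)) {
    stop(sprintf("no whisker in slice %d", slice_index), call. = FALSE)
  }
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) > 1L) {
    srt <- sort(sizes, decreasing = TRUE)
    if (srt[2] >= ambiguity_ratio * srt[1]) {
      stop(sprintf("ambiguous segmentation in slice %d: %d comparable components",
                   slice_index, sum(srt >= ambiguity_ratio * srt[1])),
           call. = FALSE)
    }
  }
  keep <- which.max(sizes)
  clean <- EBImage::fillHull(lab == keep)
  cross_section_mask(as.matrix(clean) > 0, pixel_spacing, slice_index)
}

# Pixel-center coordinates (x, y) of foreground pixels, in pixel units.
.mask_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Maximum and minimum caliper (Feret) widths of a cross-section
#'
#' The caliper width in a direction is the extent of the shape projected
#' onto that direction. The sweep runs over \[0, 180) degrees in steps of
#' 0.5 degrees on the convex hull of the foreground pixel centers; one
#' pixel spacing is added to each extent to account for pixel footprint
#' (unbiased for digitized discs). Maximum over directions is the max Feret
#' (broad aspect), minimum is the min Feret (thin aspect).
#'
#' @param mask a [cross_section_mask()].
#' @param step_deg sweep step in degrees (default 0.5).
#' @return Named numeric `c(max_caliper, min_caliper)` in micrometres.
#' @export
caliper_widths <- function(mask, step_deg = 0.5) {
  stopifnot(inherits(mask, "cross_section_mask"))
  pts <- .mask_points(mask$mask)
  if (nrow(pts) < 2L) {
    stop("degenerate geometry: single-pixel mask", call. = FALSE)
  }
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- hull %*% rbind(cos(ang), sin(ang))  # n_hull x n_angles
  extents <- (apply(proj, 2, max) - apply(proj, 2, min) + 1) *
    mask$pixel_spacing
  c(max_caliper = max(extents), min_caliper = min(extents))
}

#' Principal-axis angle (theta) of a cross-section
#'
#' Orientation of the major principal axis from the second central image
#' moments: theta = 0.5 * atan2(2*mu11, mu20 - mu02), mapped to (-90, 90]
#' degrees, measured from the slide-plane horizontal (+x, increasing toward
#' +y). For a (near-)circular section the orientation is undefined; theta
#' is reported as 0 with `circular` flag set.
#'
#' @param mask a [cross_section_mask()].
#' @param circular_tol relative tolerance on the moment anisotropy below
#'   which the section is flagged circular (default 1e-3).
#' @return A list with `theta_deg` and logical `circular`.
#' @export
principal_axis_theta <- function(mask, circular_tol = 1e-3) {
  stopifnot(inherits(mask, "cross_section_mask"))
  pts <- .mask_points(mask$mask)
  if (nrow(pts) < 2L) {
    stop("degenerate geometry: single-pixel mask", call. = FALSE)
  }
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (aniso <= circular_tol * (mu20 + mu02)) {
    return(list(theta_deg = 0, circular = TRUE))
  }
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(theta_deg = theta, circular = FALSE)
}

#' Eccentricity from caliper widths
#'
#' e = sqrt(1 - (min/max)^2): 0 for a circle, approaching (but never
#' reaching) 1 as the section flattens toward a line segment.
#'
#' @param max_caliper,min_caliper caliper widths, `max >= min > 0`.
#'   Vectorized.
#' @return Eccentricity in \[0, 1).
#' @examples
#' eccentricity(2, 1)   # 0.8660
#' @export
eccentricity <- function(max_caliper, min_caliper) {
  if (any(!is.finite(min_caliper)) || any(min_caliper <= 0)) {
    stop("min_caliper must be positive", call. = FALSE)
  }
  if (any(max_caliper < min_caliper)) {
    stop("max_caliper must be >= min_caliper", call. = FALSE)
  }
  sqrt(1 - (min_caliper / max_caliper)^2)
}

#' Per-slice metrics of one cross-section mask
#'
#' @param mask a [cross_section_mask()].
#' @return One-row data.frame: `slice_index`, `area_mm2`, `feret_max_mm`,
#'   `feret_min_mm`, `theta_deg`, `eccentricity`, `circular_flag`.
#' @export
slice_metrics <- function(mask) {
  stopifnot(inherits(mask, "cross_section_mask"))
  px_mm <- mask$pixel_spacing / 1000
  cal <- caliper_widths(mask) / 1000
  th <- principal_axis_theta(mask)
  data.frame(
    slice_index = mask$slice_index,
    area_mm2 = sum(mask$mask) * px_mm^2,
    feret_max_mm = unname(cal["max_caliper"]),
    feret_min_mm = unname(cal["min_caliper"]),
    theta_deg = th$theta_deg,
    eccentricity = eccentricity(cal["max_caliper"], cal["min_caliper"]),
    circular_flag = th$circular)
}

#' Morphometric profile along a whisker volume
#'
#' Segments every slice that contains whisker material and computes the
#' slice metrics from base to tip. The base is fixed as the largest-area
#' end of the shaft, so profiles always run thick-to-thin regardless of
#' stack orientation.
#'
#' @inheritParams segment_slice
#' @param min_pixels slices whose foreground is smaller than this are
#'   treated as empty (default 4).
#' @return A data.frame of class `shaft_profile` with one row per slice
#'   (`slice_index`, `arc_mm`, then the [slice_metrics()] columns) plus
#'   attributes `crest_indices` / `trough_indices` from
#'   [detect_crests_troughs()].
#' @export
profile_along_shaft <- function(volume,
                                threshold_policy = c("otsu", "fixed"),
                                threshold = 0.5,
                                pixel_spacing = attr(volume, "voxel_size_um"),
                                min_pixels = 4) {
  threshold_policy <- match.arg(threshold_policy)
  ns <- dim(volume)[3]
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    m <- tryCatch(
      segment_slice(volume, i, threshold_policy, threshold, pixel_spacing),
      error = function(e) {
        if (grepl("no whisker in slice", conditionMessage(e))) NULL
        else stop(sprintf("slice %d: %s", i, conditionMessage(e)),
                  call. = FALSE)
      })
    if (is.null(m) || sum(m$mask) < min_pixels) next
    rows[[i]] <- slice_metrics(m)
  }
  prof <- do.call(rbind, rows)
  if (is.null(prof) || nrow(prof) == 0L) {
    stop("volume contains no whisker", call. = FALSE)
  }
  # base = largest-area end
  n <- nrow(prof)
  head_area <- mean(prof$area_mm2[seq_len(min(5, n))])
  tail_area <- mean(prof$area_mm2[seq(max(1, n - 4), n)])
  if (tail_area > head_area) prof <- prof[rev(seq_len(n)), ]
  px_mm <- if (is.null(pixel_spacing)) NA_real_ else pixel_spacing / 1000
  prof$arc_mm <- (seq_len(n) - 1) * px_mm
  prof <- prof[, c("slice_index", "arc_mm", "area_mm2", "feret_max_mm",
                   "feret_min_mm", "theta_deg", "eccentricity",
                   "circular_flag")]
  rownames(prof) <- NULL
  ext <- detect_crests_troughs(prof$feret_max_mm)
  attr(prof, "crest_indices") <- ext$crest_indices
  attr(prof, "trough_indices") <- ext$trough_indices
  class(prof) <- c("shaft_profile", class(prof))
  prof
}

#' Detect undulation crests and troughs in a caliper series
#'
#' Local maxima (crests) and minima (troughs) of the maximum-caliper series
#' along the shaft, retained only if their prominence relative to the
#' adjacent opposite extremum exceeds a fraction of the series median.
#' Crests and troughs are forced to interleave (when two same-kind extrema
#' are adjacent the stronger one is kept). Smooth whiskers return empty
#' lists.
#'
#' @param max_caliper_series numeric series of max caliper along the shaft
#'   (length >= 5).
#' @param min_prominence_frac minimum peak-to-neighbour amplitude as a
#'   fraction of the series median (default 0.05).
#' @return List with integer `crest_indices` and `trough_indices`.
#' @export
detect_crests_troughs <- function(max_caliper_series,
                                  min_prominence_frac = 0.05) {
  x <- as.numeric(max_caliper_series)
  if (length(x) < 5L) stop("series too short (need >= 5)", call. = FALSE)
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateau extrema register once
  nz <- which(s != 0)
  if (length(nz) < 2L) {
    return(list(crest_indices = integer(0), trough_indices = integer(0)))
  }
  ext_idx <- integer(0); ext_kind <- integer(0)  # +1 crest, -1 trough
  for (k in seq_len(length(nz) - 1L)) {
    if (s[nz[k]] != s[nz[k + 1L]]) {
      ext_idx <- c(ext_idx, nz[k] + 1L)
      ext_kind <- c(ext_kind, ifelse(s[nz[k]] > 0, 1L, -1L))
    }
  }
  if (length(ext_idx) == 0L) {
    return(list(crest_indices = integer(0), trough_indices = integer(0)))
  }
  # enforce alternation: among consecutive same-kind extrema keep strongest
  keep <- rep(TRUE, length(ext_idx))
  for (k in seq_along(ext_idx)[-1]) {
    prev <- max(which(keep[seq_len(k - 1L)]))
    if (ext_kind[k] == ext_kind[prev]) {
      better_k <- (ext_kind[k] > 0) == (x[ext_idx[k]] > x[ext_idx[prev]])
      keep[if (better_k) prev else k] <- FALSE
    }
  }
  ext_idx <- ext_idx[keep]; ext_kind <- ext_kind[keep]
  # prominence: amplitude against neighbouring opposite extrema
  thr <- min_prominence_frac * stats::median(x)
  prom <- vapply(seq_along(ext_idx), function(k) {
    nb <- c(if (k > 1) x[ext_idx[k - 1]], if (k < length(ext_idx)) x[ext_idx[k + 1]])
    if (length(nb) == 0) 0 else min(abs(x[ext_idx[k]] - nb))
  }, numeric(1))
  ok <- prom >= thr
  ext_idx <- ext_idx[ok]; ext_kind <- ext_kind[ok]
  # alternation may break after prominence pruning; re-enforce
  if (length(ext_idx) > 1L) {
    keep <- rep(TRUE, length(ext_idx))
    for (k in seq_along(ext_idx)[-1]) {
      prev <- max(which(keep[seq_len(k - 1L)]))
      if (ext_kind[k] == ext_kind[prev]) {
        better_k <- (ext_kind[k] > 0) == (x[ext_idx[k]] > x[ext_idx[prev]])
        keep[if (better_k) prev else k] <- FALSE
      }
    }
    ext_idx <- ext_idx[keep]; ext_kind <- ext_kind[keep]
  }
  list(crest_indices = ext_idx[ext_kind > 0],
       trough_indices = ext_idx[ext_kind < 0])
}

#' Area vs caliper consistency across undulations
#'
#' Quantifies the observation that along an undulated whisker the
#' cross-sectional area stays nearly constant between crests and troughs
#' while the maximum caliper width oscillates. Both series are evaluated at
#' the crest and trough slices, detrended by a local linear fit (removing
#' the base-to-tip taper), and summarized as coefficients of variation
#' relative to the undetrended mean.
#'
#' @param profile a `shaft_profile` from [profile_along_shaft()], or any
#'   data.frame with `area_mm2` and `feret_max_mm` columns and crest/trough
#'   attributes (or supplied explicitly).
#' @param crest_indices,trough_indices integer indices; default taken from
#'   the profile attributes.
#' @return List with `area_cv` and `caliper_cv` (fractions), plus
#'   `n_extrema`; or a result with `applicable = FALSE` when fewer than two
#'   crests or two troughs exist.
#' @export
area_consistency_stat <- function(profile,
                                  crest_indices = attr(profile, "crest_indices"),
                                  trough_indices = attr(profile, "trough_indices")) {
  if (length(crest_indices) < 2L || length(trough_indices) < 2L) {
    return(list(applicable = FALSE, area_cv = NA_real_,
                caliper_cv = NA_real_, n_extrema = length(crest_indices) +
                  length(trough_indices)))
  }
  idx <- sort(c(crest_indices, trough_indices))
  detrended_cv <- function(y) {
    fit <- stats::lm.fit(cbind(1, idx), y)
    stats::sd(fit$residuals) / mean(y)
  }
  list(applicable = TRUE,
       area_cv = detrended_cv(profile$area_mm2[idx]),
       caliper_cv = detrended_cv(profile$feret_max_mm[idx]),
       n_extrema = length(idx))
}
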