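#' Specification of a parametric whisker phantom
#'
#' Describes a synthetic whisker shaft for voxelization: an elliptical
#' cross-section whose area follows a smooth base-to-tip taper, with either
#' a smooth surface (sea lion / fur seal archetype: constant shape, major
#' axis typically rotated away from the slide plane) or an undulated surface
#' (true seal archetype: the maximum caliper width oscillates sinusoidally
#' along the shaft while the cross-sectional area follows only the taper,
#' and the major axis stays aligned with the slide plane).
#'
#' The area profile is `A(s) = base_area * (1 - 0.2 * s/L)^taper_exponent`
#' (a 36% base-to-tip area reduction at the default exponent 2). Local
#' eccentricity ramps linearly from `base_eccentricity` to
#' `tip_eccentricity`, reproducing the increasing cross-sectional
#' flattening toward the tip. For the undulated archetype the maximum
#' semi-axis is modulated as `a(s) = a0(s) * (1 + alpha * sin(2*pi*s /
#' lambda))` and the minimum semi-axis is set to `A(s) / (pi * a(s))`, so
#' the area is untouched by the undulation.
#'
#' @param archetype `"undulated"` or `"smooth"`.
#' @param length_mm shaft length in mm (> 0).
#' @param base_area_mm2 cross-sectional area at the base in mm^2.
#' @param taper_exponent exponent of the area taper (0 = no taper).
#' @param undulation_wavelength_mm crest-to-crest wavelength in mm
#'   (undulated only).
#' @param undulation_amplitude relative modulation of the max semi-axis,
#'   in \[0, 0.5\] (undulated only; 0 disables the undulation).
#' @param base_eccentricity,tip_eccentricity eccentricity at base and tip,
#'   each in \[0, 1).
#' @param theta_profile principal-axis angle from the slide-plane
#'   horizontal, in degrees: a single number (constant along the shaft) or
#'   a function of arc position in mm. Default 0 for the undulated
#'   archetype (flattening in-plane with the shaft curvature) and 15 for
#'   the smooth archetype (profile rotated off the curvature plane).
#' @param curvature_radius_mm radius of the shaft's major curvature, used
#'   only by the bent scanner-emulation layout of [generate_phantom()].
#' @param voxel_size_um isotropic voxel pitch in micrometres (default 30).
#' @param seed integer seed (the geometry is deterministic; kept for
#'   interface symmetry with the other generators).
#' @return An object of class `whisker_spec`.
#' @export
whisker_spec <- function(archetype = c("undulated", "smooth"),
                         length_mm = 40,
                         base_area_mm2 = 0.6,
                         taper_exponent = 2,
                         undulation_wavelength_mm = 3,
                         undulation_amplitude = if (archetype == "undulated") 0.2 else 0,
                         base_eccentricity = if (archetype == "undulated") 0.80 else 0.55,
                         tip_eccentricity = if (archetype == "undulated") 0.95 else 0.85,
                         theta_profile = if (archetype == "undulated") 0 else 15,
                         curvature_radius_mm = 100,
                         voxel_size_um = 30,
                         seed = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(length_mm > 0, base_area_mm2 > 0, taper_exponent >= 0,
            undulation_wavelength_mm > 0,
            undulation_amplitude >= 0, undulation_amplitude <= 0.5,
            base_eccentricity >= 0, base_eccentricity < 1,
            tip_eccentricity >= 0, tip_eccentricity < 1,
            curvature_radius_mm > 0, voxel_size_um > 0)
  if (archetype == "smooth") undulation_amplitude <- 0
  theta_fun <- if (is.function(theta_profile)) theta_profile else {
    force(theta_profile); function(s) rep(theta_profile, length(s))
  }
  structure(list(archetype = archetype, length_mm = length_mm,
                 base_area_mm2 = base_area_mm2,
                 taper_exponent = taper_exponent,
                 undulation_wavelength_mm = undulation_wavelength_mm,
                 undulation_amplitude = undulation_amplitude,
                 base_eccentricity = base_eccentricity,
                 tip_eccentricity = tip_eccentricity,
                 theta_profile = theta_fun,
                 curvature_radius_mm = curvature_radius_mm,
                 voxel_size_um = voxel_size_um, seed = as.integer(seed)),
            class = "whisker_spec")
}

#' Analytic ground-truth profile of a whisker spec
#'
#' Evaluates the phantom geometry at given arc positions without
#' voxelizing: area, max/min caliper widths (2a, 2b of the local ellipse),
#' principal-axis angle and eccentricity. Sections where the two semi-axes
#' coincide are flagged circular (orientation undefined, theta reported 0).
#'
#' @param spec a [whisker_spec()].
#' @param s_mm arc positions in mm (default: voxel-slice centers).
#' @return data.frame with `arc_mm`, `area_mm2`, `feret_max_mm`,
#'   `feret_min_mm`, `theta_deg`, `eccentricity`, `circular_flag`.
#' @export
ground_truth_profile <- function(spec, s_mm = NULL) {
  stopifnot(inherits(spec, "whisker_spec"))
  h <- spec$voxel_size_um / 1000
  if (is.null(s_mm)) {
    s_mm <- (seq_len(floor(spec$length_mm / h)) - 0.5) * h
  }
  L <- spec$length_mm
  A <- spec$base_area_mm2 * (1 - 0.2 * s_mm / L)^spec$taper_exponent
  e <- spec$base_eccentricity +
    (spec$tip_eccentricity - spec$base_eccentricity) * s_mm / L
  b_over_a <- sqrt(1 - e^2)
  a0 <- sqrt(A / (pi * b_over_a))
  a <- a0 * (1 + spec$undulation_amplitude *
               sin(2 * pi * s_mm / spec$undulation_wavelength_mm))
  b <- A / (pi * a)
  if (any(a < b)) {
    stop(paste("invalid whisker spec: undulation amplitude swaps the",
               "major/minor axes (increase eccentricity or reduce amplitude)"),
         call. = FALSE)
  }
  circ <- abs(a - b) < 1e-12 * (a + b)
  theta <- spec$theta_profile(s_mm)
  theta[circ] <- 0
  data.frame(arc_mm = s_mm, area_mm2 = A, feret_max_mm = 2 * a,
             feret_min_mm = 2 * b, theta_deg = theta,
             eccentricity = sqrt(1 - (b / a)^2), circular_flag = circ)
}

#' Voxelize a whisker phantom
#'
#' Builds a binary voxel volume of the whisker together with its analytic
#' ground-truth profile on the same slice grid. The whisker "lies flat on
#' the slide": the slide plane is spanned by the shaft axis (slice
#' direction) and the in-slice x axis, and theta is measured from that x
#' direction within each cross-section.
#'
#' With `bend = "none"` (default) the centerline is straight along the
#' slice axis, so every axial slice of the stack is a true perpendicular
#' cross-section and the ground truth is exact slice-for-slice. With
#' `bend = "slide"` the centerline is bowed in the slide plane with radius
#' `curvature_radius_mm`, emulating raw scanner-axis slices of a curved
#' specimen (slices near the tip then cut the shaft obliquely).
#'
#' @param spec a [whisker_spec()].
#' @param bend `"none"` or `"slide"`.
#' @param min_thickness_voxels reject the spec if the thin axis of any
#'   section falls below this many voxels (default 3): the geometry would
#'   not be resolvable at the requested voxel size.
#' @return An object of class `whisker_phantom`: list with `volume`
#'   (0/1 array `[y, x, slice]`, attribute `voxel_size_um`), `truth`
#'   (ground-truth data.frame, one row per slice) and `spec`.
#' @export
generate_phantom <- function(spec, bend = c("none", "slide"),
                             min_thickness_voxels = 3) {
  stopifnot(inherits(spec, "whisker_spec"))
  bend <- match.arg(bend)
  h <- spec$voxel_size_um / 1000  # mm per voxel
  truth <- ground_truth_profile(spec)
  truth$slice_index <- seq_len(nrow(truth))
  a <- truth$feret_max_mm / 2
  b <- truth$feret_min_mm / 2
  if (any(2 * b < min_thickness_voxels * h)) {
    stop(sprintf(
      "whisker thinner than %d voxels at %.0f um voxel size: unresolvable geometry",
      min_thickness_voxels, spec$voxel_size_um), call. = FALSE)
  }
  s <- truth$arc_mm
  defl <- if (bend == "slide") {
    R <- spec$curvature_radius_mm
    if (R < spec$length_mm) {
      stop("curvature_radius_mm must be >= length_mm for the bent layout",
           call. = FALSE)
    }
    R - sqrt(R^2 - s^2)
  } else rep(0, length(s))
  a_max <- max(a)
  margin <- 3 * h
  nx <- ceiling((2 * a_max + max(defl) + 2 * margin) / h)
  ny <- ceiling((2 * a_max + 2 * margin) / h)
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  X <- matrix(xc, ny, nx, byrow = TRUE)
  Y <- matrix(yc, ny, nx)
  cy <- ny * h / 2
  theta_rad <- truth$theta_deg * pi / 180
  vol <- array(0, dim = c(ny, nx, length(s)))
  for (i in seq_along(s)) {
    cx <- margin + a_max + defl[i]
    dx <- X - cx
    dy <- Y - cy
    u <- dx * cos(theta_rad[i]) + dy * sin(theta_rad[i])
    v <- -dx * sin(theta_rad[i]) + dy * cos(theta_rad[i])
    vol[, , i] <- ((u / a[i])^2 + (v / b[i])^2 <= 1) * 1
  }
  attr(vol, "voxel_size_um") <- spec$voxel_size_um
  truth <- truth[, c("slice_index", "arc_mm", "area_mm2", "feret_max_mm",
                     "feret_min_mm", "theta_deg", "eccentricity",
                     "circular_flag")]
  structure(list(volume = vol, truth = truth, spec = spec),
            class = "whisker_phantom")
}

#' @export
print.whisker_phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf(
    "<whisker_phantom> %s archetype, %g mm, %d slices of %dx%d @ %g um\n",
    x$spec$archetype, x$spec$length_mm, d[3], d[1], d[2],
    x$spec$voxel_size_um))
  invisible(x)
}
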