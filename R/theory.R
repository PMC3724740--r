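#' Flow conditions for shedding-frequency prediction
#'
#' Bundles the free-stream velocity and kinematic viscosity used throughout
#' the vortex-shedding model. Defaults describe the flume conditions of the
#' study design this package emulates: fresh water at roughly 20 degrees C
#' flowing at 0.5 m/s.
#'
#' @param U free-stream velocity in m/s (> 0).
#' @param nu kinematic viscosity in m^2/s (> 0). 1.0e-6 is fresh water near
#'   20 degrees C.
#' @param medium free-text label for the fluid.
#' @return An object of class `flow_conditions`.
#' @examples
#' flow_conditions()          # 0.5 m/s fresh water
#' flow_conditions(U = 1.0)
#' @export
flow_conditions <- function(U = 0.5, nu = 1.0e-6, medium = "fresh water") {
  stopifnot(is.numeric(U), length(U) == 1L, U > 0,
            is.numeric(nu), length(nu) == 1L, nu > 0)
  structure(list(U = U, nu = nu, medium = medium), class = "flow_conditions")
}

#' @export
print.flow_conditions <- function(x, ...) {
  cat(sprintf("<flow_conditions> U = %g m/s, nu = %g m^2/s (%s)\n",
              x$U, x$nu, x$medium))
  invisible(x)
}

#' Reynolds number of a whisker cross-section in flow
#'
#' Re = U * d / nu, with `d` the stream-wise diameter: the cross-sectional
#' extent of the whisker perpendicular to its long axis, measured along the
#' flow direction.
#'
#' @param flow a [flow_conditions()] object.
#' @param d stream-wise diameter in metres (> 0). Vectorized.
#' @return Numeric Reynolds number(s).
#' @examples
#' reynolds(flow_conditions(), 1e-3)   # 500
#' @export
reynolds <- function(flow, d) {
  stopifnot(inherits(flow, "flow_conditions"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("stream-wise diameter `d` must be positive and finite", call. = FALSE)
  }
  flow$U * d / flow$nu
}

#' Strouhal number from an empirical Strouhal-Reynolds relation
#'
#' Empirical fits for the vortex-shedding Strouhal number of a circular
#' cylinder: a laminar-wake branch St = c0 - c_lam/Re on Re in \[50, 150\],
#' a turbulent-wake branch St = c0 - c_turb/Re on Re in \[300, 2000\], and a
#' linear blend of the two branches across the irregular transition range
#' (150, 300) so the map is continuous and total on \[50, 2000\].
#'
#' @param Re Reynolds number(s), each in \[50, 2000\].
#' @param constants named numeric vector `c(c0 = , c_lam = , c_turb = )`
#'   giving the fit constants; defaults are the classical cylinder-wake
#'   values.
#' @param blend numeric length-2, the transition interval endpoints.
#' @return A data.frame with columns `Re`, `St` and `regime` (one of
#'   `"laminar_fit"`, `"transition_blend"`, `"turbulent_fit"`).
#' @examples
#' strouhal(500)   # St = 0.212 - 2.7/500 = 0.2066
#' strouhal(100)   # St = 0.212 - 4.5/100 = 0.167
#' @export
strouhal <- function(Re,
                     constants = c(c0 = 0.212, c_lam = 4.5, c_turb = 2.7),
                     blend = c(150, 300)) {
  stopifnot(is.numeric(Re), length(Re) >= 1L,
            all(c("c0", "c_lam", "c_turb") %in% names(constants)),
            length(blend) == 2L, blend[1] < blend[2])
  if (any(!is.finite(Re)) || any(Re < 50) || any(Re > 2000)) {
    bad <- Re[!is.finite(Re) | Re < 50 | Re > 2000][1]
    stop(sprintf(
      "Reynolds number %g outside the validity range [50, 2000] (regime out_of_range)",
      bad), call. = FALSE)
  }
  st_lam  <- constants[["c0"]] - constants[["c_lam"]]  / Re
  st_turb <- constants[["c0"]] - constants[["c_turb"]] / Re
  w <- pmin(1, pmax(0, (Re - blend[1]) / (blend[2] - blend[1])))
  St <- (1 - w) * st_lam + w * st_turb
  regime <- ifelse(Re <= blend[1], "laminar_fit",
            ifelse(Re >= blend[2], "turbulent_fit", "transition_blend"))
  data.frame(Re = Re, St = St, regime = regime, stringsAsFactors = FALSE)
}

#' Predicted vortex-shedding frequency for a given stream-wise diameter
#'
#' The wake behind a bluff cylinder sheds alternating vortices at frequency
#' f = St(Re) * U / d; a whisker in flow vibrates near this forcing
#' frequency. A larger stream-wise diameter raises Re and lowers f, which is
#' why rotating the flattened whisker from thin-edge-on (0 degrees) to
#' broad-face-on (90 degrees) lowers the predicted vibration frequency.
#'
#' @inheritParams reynolds
#' @inheritParams strouhal
#' @return A data.frame (class `shedding_prediction`) with columns `d_m`,
#'   `Re`, `St`, `f_hz`, `regime`.
#' @examples
#' shedding_frequency(flow_conditions(), 1e-3)  # about 103.3 Hz
#' @export
shedding_frequency <- function(flow, d,
                               constants = c(c0 = 0.212, c_lam = 4.5, c_turb = 2.7),
                               blend = c(150, 300)) {
  Re <- reynolds(flow, d)
  st <- strouhal(Re, constants = constants, blend = blend)
  out <- data.frame(d_m = d, Re = st$Re, St = st$St,
                    f_hz = st$St * flow$U / d,
                    regime = st$regime, stringsAsFactors = FALSE)
  class(out) <- c("shedding_prediction", class(out))
  out
}

#' Shedding-frequency interval for an undulated whisker
#'
#' Undulated whiskers vary in thickness between crests and troughs, so a
#' single stream-wise diameter is ill-defined; instead the maximum and
#' minimum widths near the reference section bound the prediction. The
#' larger diameter gives the lower frequency, so `f_low` comes from `d_max`
#' and `f_high` from `d_min`. The midpoint of the interval is reported as
#' the single group-comparable scalar.
#'
#' @inheritParams reynolds
#' @param d_max,d_min maximum and minimum stream-wise diameters in metres,
#'   `d_max >= d_min > 0`.
#' @param ... passed to [shedding_frequency()].
#' @return A list with `f_low`, `f_high`, `f_mid` (Hz) and the two
#'   underlying `shedding_prediction` rows in `detail`.
#' @export
undulated_frequency_range <- function(flow, d_max, d_min, ...) {
  if (!(is.numeric(d_max) && is.numeric(d_min)) || d_min <= 0 || d_max < d_min) {
    stop("require d_max >= d_min > 0", call. = FALSE)
  }
  p_low  <- shedding_frequency(flow, d_max, ...)
  p_high <- shedding_frequency(flow, d_min, ...)
  list(f_low = p_low$f_hz, f_high = p_high$f_hz,
       f_mid = (p_low$f_hz + p_high$f_hz) / 2,
       detail = rbind(p_low, p_high))
}

#' Percent difference between measured and theoretical frequency
#'
#' 100 * |measured - theoretical| / measured. The measured value is the
#' denominator, so the statistic is not symmetric in its arguments.
#'
#' @param measured_f measured peak frequency in Hz (> 0). Vectorized.
#' @param theoretical_f predicted shedding frequency in Hz. Vectorized.
#' @return Percent difference(s) on the 0-100 scale.
#' @examples
#' percent_difference(200, 200)     # 0
#' percent_difference(100, 110)     # 10
#' percent_difference(110, 100)     # 9.0909...
#' @export
percent_difference <- function(measured_f, theoretical_f) {
  if (any(!is.finite(measured_f)) || any(measured_f <= 0)) {
    stop("measured frequency must be positive", call. = FALSE)
  }
  100 * abs(measured_f - theoretical_f) / measured_f
}
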