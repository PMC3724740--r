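#' Specification of a synthetic vibrometer recording
#'
#' Describes a shedding-tone recording as the flume produces it: a
#' deterministic fundamental tone (optionally with harmonics), a
#' low-frequency sting-mount artifact, and a white noise floor. Defaults
#' follow the rig characteristics the generator emulates: 1200 Hz sampling,
#' 6 s records, and a sting artifact confined below 50 Hz with spectral mode
#' at 15 Hz and peak spectral velocity 0.005 m/s.
#'
#' @param tone_frequency fundamental tone frequency in Hz; must be below the
#'   Nyquist frequency `sample_rate / 2`. Use 0 with `tone_amplitude = 0`
#'   for artifact-only fixtures.
#' @param tone_amplitude tone amplitude in m/s (>= 0).
#' @param harmonic_amplitudes numeric vector; amplitude of the k-th harmonic
#'   (frequency `(k + 1) * tone_frequency`) in m/s.
#' @param sample_rate Hz. @param duration seconds.
#' @param sting_peak_frequency Hz, spectral mode of the sting artifact.
#' @param sting_band_limit Hz, hard upper band edge of the sting artifact.
#' @param sting_bandwidth Hz, Gaussian half-width of the artifact's spectral
#'   shape around its mode.
#' @param sting_amplitude m/s, peak averaged-spectrum amplitude of the
#'   artifact (0 disables it).
#' @param sting_grid_hz Hz, frequency spacing of the artifact's multisine
#'   components. The default (5 Hz) matches the analysis bin grid of a
#'   240-point FFT at 1200 Hz, so the artifact is on-bin in every segment
#'   and its spectrum has exactly zero energy above `sting_band_limit`.
#' @param noise_floor m/s, standard deviation of additive white noise.
#' @param seed integer seed controlling all randomness of the realization.
#' @return An object of class `signal_spec`.
#' @seealso [generate_recording()], [sting_signal_spec()]
#' @export
signal_spec <- function(tone_frequency, tone_amplitude,
                        harmonic_amplitudes = numeric(0),
                        sample_rate = 1200, duration = 6,
                        sting_peak_frequency = 15, sting_band_limit = 50,
                        sting_bandwidth = 5, sting_amplitude = 0.005,
                        sting_grid_hz = 5, noise_floor = 0, seed = 1L) {
  stopifnot(sample_rate > 0, duration > 0,
            tone_frequency >= 0, tone_frequency < sample_rate / 2,
            tone_amplitude >= 0, all(harmonic_amplitudes >= 0),
            sting_peak_frequency < sting_band_limit,
            sting_bandwidth > 0, sting_amplitude >= 0,
            sting_grid_hz > 0, noise_floor >= 0)
  structure(list(tone_frequency = tone_frequency,
                 tone_amplitude = tone_amplitude,
                 harmonic_amplitudes = harmonic_amplitudes,
                 sample_rate = sample_rate, duration = duration,
                 sting_peak_frequency = sting_peak_frequency,
                 sting_band_limit = sting_band_limit,
                 sting_bandwidth = sting_bandwidth,
                 sting_amplitude = sting_amplitude,
                 sting_grid_hz = sting_grid_hz,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Default sting-mount artifact fixture
#'
#' A recording spec containing only the sting-mount artifact: no tone, no
#' white noise. Useful as a fixture for checking that the spectral stage
#' localizes the rig's low-frequency self-vibration (mode 15 Hz, all energy
#' below 50 Hz, peak spectral velocity 0.005 m/s).
#'
#' @param seed integer seed.
#' @param ... overrides passed to [signal_spec()].
#' @return A `signal_spec`.
#' @export
sting_signal_spec <- function(seed = 1L, ...) {
  signal_spec(tone_frequency = 0, tone_amplitude = 0, noise_floor = 0,
              seed = seed, ...)
}

# Band-limited sting artifact: a random-phase multisine on a fixed
# low-frequency grid. Component amplitudes follow a Gaussian spectral
# envelope centered at the mode, hard-zeroed above the band limit, and are
# normalized so the peak spectral amplitude equals the configured value.
# Components sit on the analysis-bin grid, so every FFT segment sees them
# on-bin: the artifact's energy is exactly zero above the band limit in the
# averaged spectrum, and its peak sits at the mode in every realization.
.sting_series <- function(t, mode_hz, limit_hz, width_hz, amplitude,
                          grid_hz) {
  if (amplitude <= 0) return(numeric(length(t)))
  f_k <- seq(grid_hz, limit_hz, by = grid_hz)
  g <- exp(-(f_k - mode_hz)^2 / (2 * width_hz^2))
  g <- g * amplitude / max(g)
  phases <- stats::runif(length(f_k), 0, 2 * pi)
  x <- numeric(length(t))
  for (k in seq_along(f_k)) {
    x <- x + g[k] * sin(2 * pi * f_k[k] * t + phases[k])
  }
  x
}

#' Generate a synthetic vibrometer recording
#'
#' Sum of (i) the deterministic fundamental tone and its harmonics, (ii) a
#' band-limited sting-mount artifact whose spectral mode sits at
#' `sting_peak_frequency` and whose energy is exactly zero above
#' `sting_band_limit`, and (iii) Gaussian white noise. Two calls with the
#' same spec (same seed) return identical sample vectors.
#'
#' @param spec a [signal_spec()].
#' @param angle_deg optional angle-of-attack annotation.
#' @param meta optional metadata list.
#' @return A [vibration_recording()] of `sample_rate * duration` samples.
#' @examples
#' rec <- generate_recording(signal_spec(200, 0.1, seed = 42))
#' peak_pick(averaged_fft(rec))
#' @export
generate_recording <- function(spec, angle_deg = NULL, meta = list()) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$sample_rate * spec$duration)
  t <- (seq_len(n) - 1) / spec$sample_rate
  x <- spec$tone_amplitude * sin(2 * pi * spec$tone_frequency * t)
  for (k in seq_along(spec$harmonic_amplitudes)) {
    x <- x + spec$harmonic_amplitudes[k] *
      sin(2 * pi * (k + 1) * spec$tone_frequency * t)
  }
  withr::with_seed(spec$seed, {
    x <- x + .sting_series(t, spec$sting_peak_frequency,
                           spec$sting_band_limit, spec$sting_bandwidth,
                           spec$sting_amplitude, spec$sting_grid_hz)
    if (spec$noise_floor > 0) x <- x + stats::rnorm(n, 0, spec$noise_floor)
  })
  vibration_recording(x, spec$sample_rate, angle_deg = angle_deg, meta = meta)
}
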