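#' Construct a vibration recording
#'
#' A single-axis point-velocity time series, as produced by a laser Doppler
#' vibrometer focused on a vibrating whisker shaft.
#'
#' @param samples numeric vector of velocities in m/s.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param angle_deg optional angle of attack (0, 45 or 90).
#' @param meta optional named list of subject metadata.
#' @return An object of class `vibration_recording`.
#' @export
vibration_recording <- function(samples, sample_rate, angle_deg = NULL,
                                meta = list()) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(sample_rate), sample_rate > 0)
  if (!is.null(angle_deg)) stopifnot(angle_deg %in% c(0, 45, 90))
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 angle_deg = angle_deg, meta = meta),
            class = "vibration_recording")
}

#' @export
print.vibration_recording <- function(x, ...) {
  cat(sprintf("<vibration_recording> %d samples @ %g Hz (%.3g s)%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$angle_deg)) "" else
                sprintf(", angle %g deg", x$angle_deg)))
  invisible(x)
}

# Split a sample vector into consecutive non-overlapping segments of nfft
# samples, dropping the remainder. Returns a nfft x n_segments matrix.
.segment_matrix <- function(samples, nfft) {
  n_seg <- length(samples) %/% nfft
  if (n_seg < 1L) {
    stop(sprintf("recording shorter than one FFT segment (%d < %d samples)",
                 length(samples), nfft), call. = FALSE)
  }
  matrix(samples[seq_len(n_seg * nfft)], nrow = nfft, ncol = n_seg)
}

#' Averaged single-sided amplitude spectrum
#'
#' Splits the recording into consecutive non-overlapping segments of `nfft`
#' samples (the remainder is discarded), computes a single-sided amplitude
#' spectrum per segment, and averages the amplitudes across segments. The
#' scaling is such that a sinusoid of amplitude A whose frequency falls
#' exactly on a bin contributes amplitude A at that bin. Frequency
#' resolution is `sample_rate / nfft`: a 6 s record at 1200 Hz analysed with
#' a 240-point FFT gives 30 averaged segments at 5 Hz resolution.
#'
#' @param recording a [vibration_recording()].
#' @param nfft FFT length in samples (default 240).
#' @param segments optional integer vector of segment indices to include
#'   (e.g. the `usable` field of [segment_quality_filter()]); default all.
#' @param window `"rectangular"` (default) or `"hann"`. The study-style
#'   minimal reading is plain segment averaging with no window.
#' @return An object of class `whisk_spectrum`: list with `frequencies`
#'   (Hz, bin centers from 0 to Nyquist), `amplitude` (m/s), `resolution`
#'   (Hz), `n_segments_averaged`, `sample_rate`, `nfft`.
#' @export
averaged_fft <- function(recording, nfft = 240, segments = NULL,
                         window = c("rectangular", "hann")) {
  stopifnot(inherits(recording, "vibration_recording"),
            is.numeric(nfft), nfft >= 4, nfft %% 2 == 0)
  window <- match.arg(window)
  seg <- .segment_matrix(recording$samples, nfft)
  n_seg_total <- ncol(seg)
  if (!is.null(segments)) {
    stopifnot(all(segments >= 1), all(segments <= n_seg_total))
    seg <- seg[, segments, drop = FALSE]
  }
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(nfft) / nfft))
  } else rep(1, nfft)
  coherent_gain <- mean(w)
  half <- nfft / 2 + 1L
  amp <- matrix(0, nrow = half, ncol = ncol(seg))
  for (j in seq_len(ncol(seg))) {
    X <- stats::fft(seg[, j] * w)
    a <- Mod(X[seq_len(half)]) / (nfft * coherent_gain)
    a[2:(half - 1L)] <- 2 * a[2:(half - 1L)]  # fold negative frequencies
    amp[, j] <- a
  }
  structure(list(
    frequencies = (0:(half - 1L)) * recording$sample_rate / nfft,
    amplitude = rowMeans(amp),
    resolution = recording$sample_rate / nfft,
    n_segments_averaged = ncol(seg),
    sample_rate = recording$sample_rate,
    nfft = nfft), class = "whisk_spectrum")
}

#' @export
print.whisk_spectrum <- function(x, ...) {
  cat(sprintf(
    "<whisk_spectrum> %d bins, resolution %g Hz, %d segment(s) averaged\n",
    length(x$frequencies), x$resolution, x$n_segments_averaged))
  invisible(x)
}

#' Peak frequency and peak velocity of a spectrum
#'
#' Arg-max of the averaged amplitude over frequency bins, always excluding
#' the 0 Hz bin (a mean offset is not a vibration) and optionally excluding
#' a frequency band — e.g. 0-50 Hz to reject the sting-mount artifact. Ties
#' are broken toward the lower frequency.
#'
#' @param spectrum a `whisk_spectrum`.
#' @param exclude_band optional numeric length-2 `c(lo, hi)` in Hz; bins with
#'   lo <= f <= hi are excluded from the search.
#' @return A list of class `peak_result`: `peak_frequency` (Hz, a bin
#'   center), `peak_velocity` (m/s), `excluded_band`.
#' @export
peak_pick <- function(spectrum, exclude_band = NULL) {
  stopifnot(inherits(spectrum, "whisk_spectrum"))
  keep <- spectrum$frequencies > 0
  if (!is.null(exclude_band)) {
    stopifnot(is.numeric(exclude_band), length(exclude_band) == 2L,
              exclude_band[1] <= exclude_band[2])
    keep <- keep & !(spectrum$frequencies >= exclude_band[1] &
                     spectrum$frequencies <= exclude_band[2])
  }
  if (!any(keep)) stop("all frequency bins excluded", call. = FALSE)
  f <- spectrum$frequencies[keep]
  a <- spectrum$amplitude[keep]
  i <- which.max(a)  # first maximum = lowest frequency on ties
  structure(list(peak_frequency = f[i], peak_velocity = a[i],
                 excluded_band = exclude_band), class = "peak_result")
}

#' Flag low-signal segments of a recording
#'
#' Some flume recordings contain stretches where the whisker moved out of
#' the laser line and the velocity signal dropped out. Segments whose RMS
#' falls below `dropout_threshold` times the median segment RMS are flagged
#' and excluded from spectral averaging.
#'
#' @inheritParams averaged_fft
#' @param dropout_threshold fraction of the median segment RMS below which a
#'   segment is flagged (default 0.25).
#' @return A list with `usable` and `flagged` segment indices, `rms` per
#'   segment and `n_segments`.
#' @export
segment_quality_filter <- function(recording, nfft = 240,
                                   dropout_threshold = 0.25) {
  stopifnot(inherits(recording, "vibration_recording"),
            dropout_threshold >= 0)
  seg <- .segment_matrix(recording$samples, nfft)
  rms <- sqrt(colMeans(seg^2))
  med <- stats::median(rms)
  flagged <- which(rms < dropout_threshold * med | rms == 0)
  if (med == 0 || length(flagged) == ncol(seg)) {
    stop("unusable recording: every segment flagged as dropout", call. = FALSE)
  }
  list(usable = setdiff(seq_len(ncol(seg)), flagged), flagged = flagged,
       rms = rms, n_segments = ncol(seg))
}
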