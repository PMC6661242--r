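#' @useDynLib ulm2d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm quantile median rnorm runif rlnorm fft setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' Transmit wavelength in micrometers
#'
#' Wavelength of the transmit pulse in soft tissue, the diffraction-scale
#' yardstick against which super-resolution gain is quoted.
#'
#' @param frequency_hz transmit frequency (Hz); 3 MHz by default.
#' @param sound_speed_m_s speed of sound (m/s); 1540 in soft tissue.
#' @return wavelength in micrometers (514 um at 3 MHz).
#' @export
us_wavelength_um <- function(frequency_hz = 3e6, sound_speed_m_s = 1540) {
  stopifnot(frequency_hz > 0, sound_speed_m_s > 0)
  sound_speed_m_s / frequency_hz * 1e6
}

#' Merge threshold: two echoes closer than 3/4 of a wavelength are one event
#' @inheritParams us_wavelength_um
#' @return distance in micrometers (385 um at 3 MHz).
#' @export
merge_threshold_um <- function(frequency_hz = 3e6, sound_speed_m_s = 1540) {
  round(0.75 * us_wavelength_um(frequency_hz, sound_speed_m_s))
}

#' Mean of detected events per frame
#'
#' Convenience for the per-frame averages quoted alongside density maps
#' (total event count over processed frame count, rounded to whole events).
#'
#' @param n_events total number of detected events.
#' @param n_frames number of processed frames.
#' @return events per frame, rounded to the nearest integer.
#' @export
events_per_frame <- function(n_events, n_frames) {
  stopifnot(n_frames > 0)
  round(n_events / n_frames)
}

# physical coordinates of pixel centers: pixel (row i, col j), 1-based,
# sits at x = (j - 0.5) * pitch, y = (i - 0.5) * pitch, origin top-left.
px_center_x <- function(col, pitch) (col - 0.5) * pitch
px_center_y <- function(row, pitch) (row - 0.5) * pitch

# deterministic fan-out of one global seed into independent stage streams
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000000L) + 1009L * as.integer(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
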