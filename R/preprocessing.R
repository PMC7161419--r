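# Filtering and derivation of the kinematic series used by all parameter
# definitions. Marker coordinates are filtered first (zero-phase Butterworth,
# 6 Hz study default), then differentiated, so measurement noise is not
# amplified by the derivative.

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward and backward (effective fourth
#' order, zero phase). The series is extended by odd reflection at both ends
#' before filtering to suppress edge transients, then trimmed.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (study value 6).
#' @param order Filter order per pass (default 2).
#' @return Filtered series, same length as the input.
#' @export
lowpass_filter <- function(series, fs, cutoff = 6, order = 2) {
  if (cutoff >= fs / 2)
    rk_abort("cutoff must be below the Nyquist frequency fs/2", "parameter")
  if (cutoff <= 0 || fs <= 0) rk_abort("fs and cutoff must be positive",
                                       "parameter")
  n <- length(series)
  pad <- ceiling(3 * fs / cutoff)
  if (n <= pad %/% 3 + 1 || n < 9)
    rk_abort("series too short for filter edge padding", "length")
  pad <- min(pad, n - 1)
  if (!all(is.finite(series))) rk_abort("series contains non-finite values",
                                        "parameter")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # symmetric reflection padding: preserves constants exactly and, unlike
  # anti-symmetric reflection, does not amplify noise gradients at the ends
  # (recordings begin and end at rest)
  padded <- c(series[(pad + 1):2], series, series[(n - 1):(n - pad)])
  out <- signal::filtfilt(bf, padded)
  out[(pad + 1):(pad + n)]
}

#' Differentiate a uniformly sampled series
#'
#' Central differences on the interior, one-sided differences at the ends.
#'
#' @param series Numeric vector (length >= 3).
#' @param fs Sampling rate in Hz.
#' @return Derivative series in input units per second.
#' @export
differentiate <- function(series, fs) {
  n <- length(series)
  if (n < 3) rk_abort("need at least 3 samples to differentiate", "length")
  d <- numeric(n)
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * fs / 2
  d[1] <- (series[2] - series[1]) * fs
  d[n] <- (series[n] - series[n - 1]) * fs
  d
}

#' Build the kinematic profile of a trial
#'
#' Filters every coordinate of every marker, then derives the series all
#' parameter definitions work from: resultant (3-D) wrist speed, its time
#' derivative (tangential acceleration; negative values are deceleration),
#' thumb–index aperture, and aperture velocity (negative while closing).
#'
#' @param rec A [trial_recording()].
#' @param cutoff Low-pass cutoff in Hz (default 6).
#' @return An object of class `kinematic_profile` with elements `t`, `fs`,
#'   `wrist_pos` (filtered, mm), `wrist_speed` (mm/s), `wrist_accel`
#'   (mm/s^2), `aperture` (mm), `aperture_vel` (mm/s).
#' @export
build_profile <- function(rec, cutoff = 6) {
  filt3 <- function(m) apply(m, 2, lowpass_filter, fs = rec$fs,
                             cutoff = cutoff)
  wrist <- filt3(rec$wrist)
  thumb <- filt3(rec$thumb)
  index <- filt3(rec$index)
  vel <- apply(wrist, 2, differentiate, fs = rec$fs)
  speed <- sqrt(rowSums(vel^2))
  accel <- differentiate(speed, rec$fs)
  aperture <- sqrt(rowSums((thumb - index)^2))
  aperture_vel <- differentiate(aperture, rec$fs)
  structure(
    list(t = rec$t, fs = rec$fs, wrist_pos = wrist, wrist_speed = speed,
         wrist_accel = accel, aperture = aperture,
         aperture_vel = aperture_vel),
    class = "kinematic_profile")
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat(sprintf(
    "<kinematic_profile> %d samples @ %g Hz | peak speed %.1f mm/s | peak aperture %.1f mm\n",
    length(x$t), x$fs, max(x$wrist_speed), max(x$aperture)))
  invisible(x)
}
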