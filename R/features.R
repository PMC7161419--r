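# Movement segmentation and extraction of the eleven kinematic parameters.
#
# Movement time runs from movement onset (first sample at which the resultant
# wrist speed exceeds 5 mm/s and stays above it for more than 500 ms) to grip
# offset (the moment the grip closing velocity, having exceeded 5 mm/s after
# maximum aperture, drops back below it — fingertip contact). Peak times are
# normalised by movement time, onset mapped to 0.

#' Detect movement onset
#'
#' Earliest index `i` with `speed[i] > threshold` and `speed[j] > threshold`
#' for all `j` in `i .. i + round(sustain * fs)` (left-to-right scan).
#'
#' @param wrist_speed Resultant wrist speed in mm/s.
#' @param fs Sampling rate in Hz.
#' @param threshold Onset threshold in mm/s (study value 5).
#' @param sustain Required supra-threshold duration in seconds (study value
#'   0.5).
#' @return Onset sample index.
#' @export
detect_movement_onset <- function(wrist_speed, fs, threshold = 5,
                                  sustain = 0.5) {
  n <- length(wrist_speed)
  k <- as.integer(round(sustain * fs))
  if (n <= k) rk_abort("series shorter than the onset sustain window",
                       "length")
  above <- wrist_speed > threshold
  # run length of consecutive TRUEs starting at each index, computed backwards
  run <- integer(n)
  run[n] <- as.integer(above[n])
  for (i in (n - 1):1) run[i] <- if (above[i]) run[i + 1] + 1L else 0L
  hit <- which(run >= k + 1L)
  if (!length(hit)) rk_abort("no sustained movement onset found",
                             "no_movement")
  hit[1]
}

#' Detect grip offset (fingertip contact)
#'
#' Scans the closing velocity (`-aperture_vel`) after `after_idx` (the sample
#' of maximum grip aperture): finds the first index where it exceeds
#' `threshold`, then returns the first later index where it drops back below.
#' With several closing pulses this is the end of the first supra-threshold
#' pulse — contact terminates the movement.
#'
#' @param aperture_vel Aperture velocity in mm/s (negative while closing).
#' @param fs Sampling rate in Hz.
#' @param after_idx Sample index of maximum grip aperture.
#' @param threshold Closing-velocity threshold in mm/s (study value 5).
#' @return Offset sample index.
#' @export
detect_grip_offset <- function(aperture_vel, fs, after_idx, threshold = 5) {
  n <- length(aperture_vel)
  if (after_idx >= n - 1) rk_abort("no samples after maximum aperture",
                                   "no_contact")
  closing <- -aperture_vel
  i <- after_idx + 1L
  while (i <= n && closing[i] <= threshold) i <- i + 1L
  if (i > n) rk_abort("closing velocity never exceeds threshold after MGA",
                      "no_contact")
  while (i <= n && closing[i] > threshold) i <- i + 1L
  if (i > n) rk_abort("closing velocity never drops back below threshold",
                      "no_contact")
  i
}

#' Segment a trial into its movement
#'
#' Combines onset and offset detection; maximum grip aperture is located
#' between onset and the end of the recording and grip offset is searched
#' after it.
#'
#' @param profile A [build_profile()] result.
#' @param onset_threshold,offset_threshold Thresholds in mm/s (default 5).
#' @param sustain Onset sustain requirement in seconds (default 0.5).
#' @return An object of class `movement_segment` with `onset_idx`,
#'   `offset_idx`, `movement_time` (s), `fs`.
#' @export
segment_movement <- function(profile, onset_threshold = 5,
                             offset_threshold = 5, sustain = 0.5) {
  onset <- detect_movement_onset(profile$wrist_speed, profile$fs,
                                 onset_threshold, sustain)
  n <- length(profile$t)
  mga_idx <- onset - 1L + which.max(profile$aperture[onset:n])
  offset <- detect_grip_offset(profile$aperture_vel, profile$fs, mga_idx,
                               offset_threshold)
  if (onset >= offset)
    rk_abort("movement onset not earlier than grip offset", "segmentation")
  movement_segment(onset, offset, profile$fs)
}

#' @rdname segment_movement
#' @param onset_idx,offset_idx Sample indices delimiting the movement.
#' @param fs Sampling rate in Hz.
#' @export
movement_segment <- function(onset_idx, offset_idx, fs) {
  if (onset_idx >= offset_idx)
    rk_abort("onset_idx must be smaller than offset_idx", "segmentation")
  structure(list(onset_idx = as.integer(onset_idx),
                 offset_idx = as.integer(offset_idx),
                 movement_time = (offset_idx - onset_idx) / fs, fs = fs),
            class = "movement_segment")
}

#' Maximum trajectory deviation of the wrist path
#'
#' Per-sample 3-D distance of the wrist from the straight line joining the
#' positions at movement onset and grip offset. The magnitude of the maximum
#' is signed by the horizontal component of the deviation vector along
#' `normalize(cross(movement direction, vertical))`: positive = rightward.
#'
#' @param wrist_pos n x 3 matrix of (filtered) wrist positions in mm.
#' @param segment A [movement_segment()].
#' @return List with `MTD` (signed mm) and `TMTD` (proportion of movement
#'   time at which the maximum occurs).
#' @export
trajectory_deviation <- function(wrist_pos, segment) {
  i0 <- segment$onset_idx
  i1 <- segment$offset_idx
  p0 <- wrist_pos[i0, ]
  p1 <- wrist_pos[i1, ]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-9)
    rk_abort("start and end positions coincide; deviation line undefined",
             "degenerate_line")
  dhat <- d / len
  pts <- sweep(wrist_pos[i0:i1, , drop = FALSE], 2, p0)
  along <- pts %*% dhat
  perp <- pts - along %*% t(dhat)
  dist <- sqrt(rowSums(perp^2))
  k <- which.max(dist)
  up <- c(0, 1, 0)
  u <- c(dhat[2] * up[3] - dhat[3] * up[2],
         dhat[3] * up[1] - dhat[1] * up[3],
         dhat[1] * up[2] - dhat[2] * up[1])
  un <- sqrt(sum(u^2))
  sgn <- if (un < 1e-9) 1 else sign(sum(perp[k, ] * (u / un)))
  if (sgn == 0) sgn <- 1
  list(MTD = sgn * dist[k],
       TMTD = (k - 1) / (segment$offset_idx - segment$onset_idx))
}

#' Extract the eleven kinematic parameters of a trial
#'
#' All extrema are searched within the movement segment. `MWDec` is the
#' magnitude of the most negative tangential acceleration after the wrist
#' speed peak (deceleration phase); `MGCV` is the peak closing velocity after
#' the maximum-aperture sample. Peak times are proportions of movement time.
#' Extrema falling on a segment boundary are flagged in the `flags` column
#' (comma-separated), not errors.
#'
#' @param profile A [build_profile()] result.
#' @param segment A [movement_segment()].
#' @return One-row data frame with columns `MT` (s), `MWV` (m/s), `MWDec`
#'   (m/s^2, positive magnitude), `MTD` (signed mm), `MGA` (mm), `MGCV`
#'   (m/s), `TMWV`, `TMWDec`, `TMTD`, `TMGA`, `TMGCV` (proportions), `flags`.
#' @export
extract_parameters <- function(profile, segment) {
  i0 <- segment$onset_idx
  i1 <- segment$offset_idx
  span <- i1 - i0
  flags <- character()
  norm_t <- function(idx) (idx - i0) / span

  speed <- profile$wrist_speed
  v_idx <- i0 - 1L + which.max(speed[i0:i1])
  if (v_idx %in% c(i0, i1)) flags <- c(flags, "MWV_boundary")
  mwv <- speed[v_idx]

  accel <- profile$wrist_accel
  d_idx <- v_idx - 1L + which.min(accel[v_idx:i1])
  if (d_idx %in% c(v_idx, i1)) flags <- c(flags, "MWDec_boundary")
  mwdec <- -accel[d_idx]

  ap <- profile$aperture
  g_idx <- i0 - 1L + which.max(ap[i0:i1])
  if (g_idx %in% c(i0, i1)) flags <- c(flags, "MGA_boundary")
  mga <- ap[g_idx]

  closing <- -profile$aperture_vel
  c_idx <- g_idx - 1L + which.max(closing[g_idx:i1])
  if (c_idx %in% c(g_idx, i1)) flags <- c(flags, "MGCV_boundary")
  mgcv <- closing[c_idx]

  dev <- trajectory_deviation(profile$wrist_pos, segment)

  data.frame(
    MT = segment$movement_time,
    MWV = mwv / 1000, MWDec = mwdec / 1000, MTD = dev$MTD, MGA = mga,
    MGCV = mgcv / 1000,
    TMWV = norm_t(v_idx), TMWDec = norm_t(d_idx), TMTD = dev$TMTD,
    TMGA = norm_t(g_idx), TMGCV = norm_t(c_idx),
    flags = paste(flags, collapse = ","))
}

#' Full extraction for one recording
#'
#' Convenience wrapper: profile construction, segmentation, parameter
#' extraction, and attachment of trial metadata.
#'
#' @param rec A [trial_recording()].
#' @param cutoff Low-pass cutoff in Hz.
#' @param onset_threshold,offset_threshold,sustain Segmentation settings, see
#'   [segment_movement()].
#' @return One-row data frame: participant, group, condition, trial, the
#'   eleven parameters, flags.
#' @export
extract_trial <- function(rec, cutoff = 6, onset_threshold = 5,
                          offset_threshold = 5, sustain = 0.5) {
  profile <- build_profile(rec, cutoff = cutoff)
  seg <- segment_movement(profile, onset_threshold, offset_threshold, sustain)
  pars <- extract_parameters(profile, seg)
  cbind(data.frame(participant = rec$participant_id, group = rec$group,
                   condition = rec$condition, trial = rec$trial_index),
        pars)
}
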