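# Synthetic reach-to-grasp trials, cohorts and CPT sessions with exported
# ground truth.
#
# The wrist transport follows either a pure minimum-jerk profile (default) or
# a target-driven profile: a smoothstep rise to the requested peak speed,
# followed by a deceleration phase whose tangential-acceleration pulse is a
# unit-peak beta bump placed so the deceleration peak lands at the requested
# normalised time. The wrist traverses an arclength-parameterised path (a
# straight reach with an optional single-lobe lateral deviation bump), so the
# designed speed profile IS the resultant speed and all transport parameters
# are exact closed forms. The grip aperture rises from 20 mm (thumb and index
# gently in opposition) to the requested maximum and closes onto the 75 mm
# cylinder via a beta-bump closing-velocity pulse solved so that the peak
# closing velocity, its timing, and the 5 mm/s contact crossing all hit their
# targets.
#
# Two notions of truth are exported per trial: the analytic clean-trajectory
# parameters (`profile_truth`) and the noise-free pipeline measurement
# (`ground_truth`): the 6 Hz zero-phase filter and the threshold rules leave
# small deterministic shifts (most visibly ~30 ms at the abrupt contact
# event) that belong to the measurement chain, not to marker noise, so
# recovery error is assessed against the noise-free measurement.

OBJECT_DIAMETER <- 75    # mm, grasped cylinder
APERTURE_CONTACT <- 95   # mm, thumb-index marker distance at contact: the
                         # 75 mm cylinder plus finger-pad / nail-marker offset
APERTURE_REST <- 20      # mm, thumb-index distance on the start pad
MINJERK_PEAK_COEF <- 1.875        # peak speed = 1.875 * D / MT
MINJERK_DECEL_COEF <- 5.7735027   # peak |decel| = 5.7735 * D / MT^2
MINJERK_DECEL_TAU <- (1 + 1 / sqrt(3)) / 2  # 0.7886751, decel-peak time

#' Specification of one synthetic reach-to-grasp trial
#'
#' With `targets = NULL` the transport is a pure minimum-jerk reach of length
#' `distance` completed in `mt` seconds (peak speed `1.875 * distance / mt`
#' at the midpoint). Supplying `targets` (named vector/list with entries
#' `MT`, `MWV`, `TMWV`, `MWDec`, `TMWDec`, `MTD`, `TMTD`, `MGA`, `TMGA`,
#' `MGCV`, `TMGCV` in reported units) switches to the target-driven profile
#' used by [gen_cohort()], solved so every clean-trajectory parameter equals
#' its target.
#'
#' @param mt Movement time in s (> 0.7).
#' @param distance Reach distance in mm (study geometry: 350).
#' @param fs Sampling rate in Hz (study value 140).
#' @param mga Maximum grip aperture target, mm (> 75).
#' @param tmga,tmgcv Normalised times of maximum aperture and peak closing
#'   velocity.
#' @param mgcv Peak grip closing velocity in m/s.
#' @param deviation_amp Signed lateral deviation amplitude in mm (positive =
#'   rightward).
#' @param deviation_peak_tau Normalised time of the deviation maximum.
#' @param noise_sd Marker noise SD per axis in mm, length-3 (x, y, z);
#'   apparatus values c(0.3, 0.2, 0.3).
#' @param pre_pad,post_pad Rest padding before onset / after contact, s.
#' @param seed Integer seed for the marker noise.
#' @param targets Optional full 11-parameter target set (see above).
#' @return A `trial_spec` list.
#' @export
trial_spec <- function(mt = 1.3, distance = 350, fs = 140,
                       mga = 127, tmga = 0.70, mgcv = 0.18, tmgcv = 0.85,
                       deviation_amp = 0, deviation_peak_tau = 0.45,
                       noise_sd = c(0.3, 0.2, 0.3),
                       pre_pad = 0.6, post_pad = 0.6, seed = 1L,
                       targets = NULL) {
  sp <- list(mt = mt, distance = distance, fs = fs, mga = mga, tmga = tmga,
             mgcv = mgcv, tmgcv = tmgcv, deviation_amp = deviation_amp,
             deviation_peak_tau = deviation_peak_tau,
             noise_sd = rep_len(noise_sd, 3), pre_pad = pre_pad,
             post_pad = post_pad, seed = seed, targets = targets)
  if (!is.null(targets)) {
    targets <- as.list(targets)
    miss <- setdiff(PARAM_NAMES, names(targets))
    if (length(miss))
      rk_abort(paste("targets missing:", paste(miss, collapse = ", ")), "spec")
    sp$mt <- targets$MT
    sp$mga <- targets$MGA
    sp$tmga <- targets$TMGA
    sp$mgcv <- targets$MGCV
    sp$tmgcv <- targets$TMGCV
    sp$deviation_amp <- targets$MTD
    sp$deviation_peak_tau <- targets$TMTD
    sp$targets <- targets
  }
  if (sp$mt <= 0.7) rk_abort("movement time must exceed 0.7 s", "spec")
  if (sp$mga <= APERTURE_CONTACT + 5)
    rk_abort("maximum grip aperture must exceed the aperture at contact",
             "spec")
  if (sp$tmga <= 0 || sp$tmga >= 1 || sp$tmgcv <= sp$tmga || sp$tmgcv >= 1)
    rk_abort("need 0 < TMGA < TMGCV < 1", "spec")
  if (sp$fs <= 0 || sp$distance <= 0) rk_abort("fs and distance must be positive", "spec")
  class(sp) <- "trial_spec"
  sp
}

# ---- internal solvers ------------------------------------------------------

# Closing-velocity pulse: unit-peak beta bump scaled to peak `v_peak` mm/s at
# time t_gcv on [t_ga, t_c], integrating to `amp` mm, with its downward 5 mm/s
# crossing exactly at t_off. Solves (t_c, kappa).
solve_closing <- function(amp, t_ga, v_peak, t_gcv, t_off, thr = 5) {
  if (amp <= 0) rk_abort("aperture must close by a positive amount", "spec")
  if (v_peak <= 2 * thr)
    rk_abort("closing-velocity target too close to the contact threshold",
             "spec")
  if (t_gcv <= t_ga || t_gcv >= t_off)
    rk_abort("peak closing velocity must fall between MGA and contact",
             "spec")
  kap_min <- 1  # keep the pulse peak curved enough for a stable argmax
  solve_at <- function(t_c) {
    dur <- t_c - t_ga
    m <- (t_gcv - t_ga) / dur
    rho <- amp / (dur * v_peak)
    if (rho >= 0.995 || rho <= 0.005 || m <= 0.01 || m >= 0.99)
      return(NULL)
    kap <- tryCatch(
      exp(stats::uniroot(function(lk) beta_bump_int(1, m, exp(lk)) - rho,
                         c(log(1e-3), log(3000)), tol = 1e-11)$root),
      error = function(e) NULL)
    if (is.null(kap) || kap < kap_min) return(NULL)
    # with a very flat pulse (small kappa) the tail may still exceed the
    # threshold numerically at u ~ 1: the crossing then sits at the pulse end
    u_cross <- if (beta_bump(1 - 1e-12, m, kap) >= thr / v_peak) 1 else
      stats::uniroot(function(u) beta_bump(u, m, kap) - thr / v_peak,
                     c(m, 1 - 1e-12), tol = 1e-13)$root
    list(t_c = t_c, m = m, kappa = kap,
         gap = (t_ga + u_cross * dur) - t_off)
  }
  grid <- seq(t_off + 1e-4, t_off + 2.5 * (t_off - t_ga), length.out = 80)
  prev <- NULL
  sol <- NULL
  best <- NULL
  for (tc in grid) {
    cur <- solve_at(tc)
    if (is.null(cur)) { prev <- NULL; next }
    if (is.null(best) || abs(cur$gap) < abs(best$gap)) best <- cur
    if (!is.null(prev) && prev$gap <= 0 && cur$gap >= 0) {
      tcr <- stats::uniroot(function(t) solve_at(t)$gap,
                            c(prev$t_c, cur$t_c), tol = 1e-10)$root
      sol <- solve_at(tcr)
      break
    }
    if (abs(cur$gap) < 1e-9) { sol <- cur; break }
    prev <- cur
  }
  # when the exact crossing time cannot be met (near-flat pulses pinned at
  # their feasibility boundary), take the closest achievable crossing
  if (is.null(sol) && !is.null(best) &&
      abs(best$gap) <= 0.3 * (t_off - t_ga)) sol <- best
  if (is.null(sol))
    rk_abort("no feasible closing pulse for these aperture targets", "spec")
  sol$v_peak <- v_peak
  sol$t_ga <- t_ga
  sol
}

# Target-driven transport: smoothstep rise to mwv at t_v, beta-bump
# deceleration peaking at mwdec at t_d, speed reaching zero at t_e. The
# deceleration bump uses kappa = 1/m (linear take-off), which keeps the speed
# maximum locally quadratic rather than flat — a flat peak would bias its
# detected time under noise. Times are absolute (movement starts at t = 0);
# the thr crossing gives onset.
solve_transport_targets <- function(mwv, tmwv, mwdec, tmwdec, mt, thr = 5) {
  if (tmwv <= 0.02 || tmwdec <= tmwv + 0.02 || tmwdec >= 0.98)
    rk_abort("need 0 < TMWV < TMWDec < 1 with margin", "spec")
  if (mwv <= 4 * thr) rk_abort("peak wrist speed target too small", "spec")
  u0 <- stats::uniroot(function(u) mwv * smoothstep(u) - thr,
                       c(1e-9, 1), tol = 1e-13)$root
  delta <- 0
  for (i in 1:12) {
    t_v <- delta + tmwv * mt
    delta_new <- u0 * t_v
    if (abs(delta_new - delta) < 1e-12) { delta <- delta_new; break }
    delta <- delta_new
  }
  t_v <- delta + tmwv * mt
  t_d <- delta + tmwdec * mt
  t_off <- delta + mt
  f <- function(Delta) {
    m <- (t_d - t_v) / Delta
    mwdec * Delta * beta_bump_int(1, m, 1 / m) - mwv
  }
  lo <- (t_d - t_v) / (1 - 1e-4)
  if (f(lo) > 0 || f(60) < 0)
    rk_abort("transport targets infeasible: deceleration peak inconsistent with its timing",
             "spec")
  Delta <- stats::uniroot(f, c(lo, 60), tol = 1e-12)$root
  t_e <- t_v + Delta
  if (t_e > t_off - 1e-6)
    rk_abort("transport does not finish before contact", "spec")
  m <- (t_d - t_v) / Delta
  kappa <- 1 / m
  L <- mwv * t_v * smoothstep_int(1) +
    mwv * Delta - mwdec * Delta^2 *
      (1 * beta_bump_int(1, m, kappa) - beta_bump_int_t(1, m, kappa))
  speed <- function(t) {
    out <- numeric(length(t))
    r <- t > 0 & t <= t_v
    out[r] <- mwv * smoothstep(t[r] / t_v)
    d <- t > t_v & t < t_e
    out[d] <- mwv - mwdec * Delta *
      beta_bump_int((t[d] - t_v) / Delta, m, kappa)
    pmax(out, 0)
  }
  arclen <- function(t) {
    out <- numeric(length(t))
    r <- t > 0 & t <= t_v
    out[r] <- mwv * t_v * smoothstep_int(t[r] / t_v)
    d <- t > t_v & t < t_e
    u <- (t[d] - t_v) / Delta
    out[d] <- mwv * t_v * smoothstep_int(1) + mwv * (t[d] - t_v) -
      mwdec * Delta^2 *
        (u * beta_bump_int(u, m, kappa) - beta_bump_int_t(u, m, kappa))
    out[t >= t_e] <- L
    out
  }
  # time at which the decelerating speed drops below thr (sustain check)
  t_s5 <- tryCatch(
    stats::uniroot(function(t) speed(t) - thr, c(t_v + 1e-9, t_e - 1e-9),
                   tol = 1e-12)$root,
    error = function(e)
      rk_abort("transport speed profile leaves no threshold crossing", "spec"))
  if (t_s5 - delta < 0.5 + 0.02)
    rk_abort("speed not sustained above threshold for 500 ms", "spec")
  list(speed = speed, arclen = arclen, L = L, t_on = delta, t_v = t_v,
       t_d = t_d, t_e = t_e, t_off = t_off, mwv = mwv, mwdec = mwdec)
}

# Pure minimum-jerk transport over [0, mt], reach length D.
solve_transport_minjerk <- function(D, mt, thr = 5) {
  mwv <- MINJERK_PEAK_COEF * D / mt
  speed <- function(t) {
    tau <- pmin(pmax(t / mt, 0), 1)
    D / mt * 30 * tau^2 * (1 - tau)^2
  }
  arclen <- function(t) {
    tau <- pmin(pmax(t / mt, 0), 1)
    D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  delta <- stats::uniroot(function(t) speed(t) - thr, c(1e-9, mt / 2),
                          tol = 1e-13)$root
  if (mt - 2 * delta < 0.5 + 0.02)
    rk_abort("speed not sustained above threshold for 500 ms", "spec")
  list(speed = speed, arclen = arclen, L = D, t_on = delta, t_v = mt / 2,
       t_d = MINJERK_DECEL_TAU * mt, t_e = mt, t_off = mt, mwv = mwv,
       mwdec = MINJERK_DECEL_COEF * D / mt^2)
}

# Full clean-trial model for a spec: transport + aperture + deviation +
# threshold-based ground truth.
solve_clean_trial <- function(spec, thr = 5) {
  tg <- spec$targets
  if (is.null(tg)) {
    tr <- solve_transport_minjerk(spec$distance, spec$mt, thr)
    t_ga <- spec$tmga * spec$mt
    t_gcv <- spec$tmgcv * spec$mt
    t_dev <- spec$deviation_peak_tau * spec$mt
  } else {
    tr <- solve_transport_targets(tg$MWV * 1000, tg$TMWV, tg$MWDec * 1000,
                                  tg$TMWDec, tg$MT, thr)
    t_ga <- tr$t_on + tg$TMGA * tg$MT
    t_gcv <- tr$t_on + tg$TMGCV * tg$MT
    t_dev <- tr$t_on + tg$TMTD * tg$MT
  }
  # Aperture: an opening velocity lobe (sin^2) and the closing-velocity pulse
  # overlap around the aperture maximum, so the aperture velocity crosses
  # zero transversally there — a flat-topped aperture peak would make the
  # detected TMGA unstable. The opening amplitude is solved so the peak hits
  # the requested maximum aperture and the net closure ends exactly at the
  # contact aperture.
  t_overlap <- 0.25 * (t_gcv - t_ga)
  t_cs <- max(t_ga - t_overlap, 0.5 * t_ga)
  T_o <- t_ga + t_overlap
  open_int <- function(t, V_o) {
    tt <- pmin(pmax(t, 0), T_o)
    V_o * (tt / 2 - T_o / (4 * pi) * sin(2 * pi * tt / T_o))
  }
  close_amp <- APERTURE_CONTACT - APERTURE_REST
  V_o <- 2 * (spec$mga - APERTURE_REST) / T_o * 1.05
  cl <- NULL
  for (it in 1:5) {
    amp_c <- V_o * T_o / 2 - close_amp
    if (amp_c <= 1)
      rk_abort("aperture targets leave no room for a closing pulse", "spec")
    cl <- solve_closing(amp_c, t_cs, spec$mgcv * 1000, t_gcv, tr$t_off, thr)
    dur <- cl$t_c - t_cs
    tg_dense <- seq(t_cs, T_o, length.out = 400)
    ap_dense <- APERTURE_REST + open_int(tg_dense, V_o) -
      cl$v_peak * dur *
        beta_bump_int((tg_dense - t_cs) / dur, cl$m, cl$kappa)
    ap_max <- max(ap_dense)
    if (abs(ap_max - spec$mga) < 1e-4) break
    V_o <- V_o * (spec$mga - APERTURE_REST) / (ap_max - APERTURE_REST)
  }
  dur_c <- cl$t_c - t_cs
  close_int <- function(t) {
    u <- pmin(pmax((t - t_cs) / dur_c, 0), 1)
    cl$v_peak * dur_c * beta_bump_int(u, cl$m, cl$kappa)
  }
  aperture <- function(t) {
    out <- APERTURE_REST + open_int(t, V_o) - close_int(t)
    out[t <= 0] <- APERTURE_REST
    out
  }
  aperture_vel <- function(t) {
    o <- numeric(length(t))
    op <- t > 0 & t < T_o
    o[op] <- V_o * sin(pi * t[op] / T_o)^2
    csel <- t > t_cs & t < cl$t_c
    o[csel] <- o[csel] -
      cl$v_peak * beta_bump((t[csel] - t_cs) / dur_c, cl$m, cl$kappa)
    o
  }
  # actual aperture-peak time (opening and closing velocities equal)
  t_ap_peak <- tryCatch(
    stats::uniroot(function(t) aperture_vel(t), c(t_cs + 1e-6, T_o - 1e-6),
                   tol = 1e-10)$root,
    error = function(e) t_ga)

  # Lateral deviation: a smooth single-lobe bump in arc fraction, so the
  # lateral motion slows down with the wrist and the designed speed profile
  # remains the exact resultant speed (the forward coordinate absorbs the
  # lateral excursion through the arclength constraint).
  amp <- spec$deviation_amp
  if (abs(amp) > 1e-12) {
    if (t_dev <= tr$t_on + 1e-6 || t_dev >= tr$t_e - 1e-6)
      rk_abort("deviation peak must occur while the wrist is moving", "spec")
    f_star <- tr$arclen(t_dev) / tr$L
    if (f_star <= 0.05 || f_star >= 0.95)
      rk_abort("deviation peak too close to the path ends", "spec")
    # warped-sine bow: infinitely smooth over the whole path, zero slope at
    # both ends, peak placed at f_star via the warp exponent; smoothness
    # keeps the marker components band-limited so the measurement filter
    # does not distort them
    gam <- log(0.5) / log(f_star)
    dev_bump <- function(f) sin(pi * pmin(pmax(f, 0), 1)^gam)^2
    fg <- seq(0, 1, length.out = 2001)
    zg <- amp * dev_bump(fg)
    dz <- c(diff(zg) / diff(fg), 0) / tr$L
    if (max(abs(dz)) >= 0.9)
      rk_abort("deviation amplitude too large for the path length", "spec")
    xg <- tr$L * cumtrapz(fg, sqrt(pmax(1 - dz^2, 0)))
    pos_xz <- function(t) {
      f <- pmin(pmax(tr$arclen(t) / tr$L, 0), 1)
      cbind(stats::approx(fg, xg, f)$y, amp * dev_bump(f))
    }
  } else {
    pos_xz <- function(t) cbind(tr$arclen(t), numeric(length(t)))
  }

  mt_gt <- tr$t_off - tr$t_on
  gt <- data.frame(
    MT = mt_gt, MWV = tr$mwv / 1000, MWDec = tr$mwdec / 1000,
    MTD = amp, MGA = spec$mga, MGCV = cl$v_peak / 1000,
    TMWV = (tr$t_v - tr$t_on) / mt_gt,
    TMWDec = (tr$t_d - tr$t_on) / mt_gt,
    TMTD = if (abs(amp) > 1e-12) (t_dev - tr$t_on) / mt_gt else NA_real_,
    TMGA = (t_ap_peak - tr$t_on) / mt_gt,
    TMGCV = (t_gcv - tr$t_on) / mt_gt)

  list(transport = tr, closing = cl, aperture = aperture,
       aperture_vel = aperture_vel, pos_xz = pos_xz, t_ga = t_ga,
       t_gcv = t_gcv, t_dev = t_dev, t_c = cl$t_c, ground_truth = gt)
}

# ---- trial generation ------------------------------------------------------

#' Generate a synthetic reach-to-grasp trial
#'
#' Renders the clean trial defined by `spec` at `spec$fs` and adds
#' independent Gaussian marker noise per axis and sample. Two notions of
#' truth are returned: `profile_truth` holds the analytic clean-trajectory
#' parameters (threshold definitions evaluated on the continuous profile),
#' while `ground_truth` is the noise-free measurement — the extraction
#' pipeline (6 Hz zero-phase filter, central differences, threshold
#' segmentation) applied to the clean sampled recording. Parameter-recovery
#' error against `ground_truth` therefore isolates what marker noise adds;
#' the small systematic filter/discretisation shifts live in the difference
#' between the two truths.
#'
#' @param spec A [trial_spec()].
#' @param participant_id,group,condition,trial_index Metadata attached to the
#'   recording.
#' @return List of class `reach_trial`: `recording` ([trial_recording()]),
#'   `ground_truth` (noise-free pipeline measurement, one row),
#'   `profile_truth` (analytic clean-trajectory parameters, one row),
#'   `truth_times` (onset/contact times and sample indices, including the
#'   nominal movement interval), `spec`.
#' @export
gen_reach_trial <- function(spec, participant_id = "S01", group = "TC",
                            condition = "A", trial_index = 1L) {
  model <- solve_clean_trial(spec)
  tr <- model$transport
  n <- ceiling((spec$pre_pad + model$t_c + spec$post_pad) * spec$fs) + 1
  t <- (seq_len(n) - 1) / spec$fs - spec$pre_pad

  xz <- model$pos_xz(t)
  wrist <- cbind(xz[, 1], 0, xz[, 2])
  ap <- model$aperture(t)
  grip <- sweep(wrist, 2, c(60, 40, 0), "+")
  ap_dir <- c(0, 0.8, 0.6)
  thumb <- grip - outer(ap / 2, ap_dir)
  index <- grip + outer(ap / 2, ap_dir)

  rec <- trial_recording(participant_id, group, condition, trial_index,
                         spec$fs, t - t[1], wrist, thumb, index)
  gt <- tryCatch(
    extract_trial(rec)[PARAM_NAMES],
    error = function(e)
      rk_abort(paste("clean trial not measurable:", conditionMessage(e)),
               "spec"))
  out_rec <- if (any(spec$noise_sd > 0))
    add_marker_noise(rec, spec$noise_sd, spec$seed) else rec

  truth_times <- list(
    t_on = tr$t_on, t_off = tr$t_off, t_contact = model$t_c,
    onset_idx = which(t >= tr$t_on)[1],
    offset_idx = which(t >= tr$t_off)[1],
    nominal_start_idx = which(t >= 0)[1],
    nominal_end_idx = max(which(t <= tr$t_off)))
  structure(list(recording = out_rec, ground_truth = gt,
                 profile_truth = model$ground_truth,
                 truth_times = truth_times, spec = spec),
            class = "reach_trial")
}

# One-to-two-pass calibration: nudge the requested targets so that the
# noise-free pipeline measurement of the generated trial lands on them
# (compensates the deterministic filter/threshold shifts of the 6 Hz
# measurement chain).
calibrate_targets <- function(targets, fs = 140, iterations = 6,
                              damping = 0.85) {
  want <- as.list(targets)
  adj <- want
  measure <- function(a) tryCatch({
    sp <- trial_spec(fs = fs, noise_sd = c(0, 0, 0), targets = a)
    gen_reach_trial(sp)$ground_truth
  }, reachkin_spec_error = function(e) NULL)
  meas <- measure(adj)
  if (is.null(meas)) rk_abort("targets infeasible", "spec")
  score <- function(m) {
    ap <- c("MWV", "MWDec", "MGA", "MGCV", "MTD")
    tp <- c("MT", "TMWV", "TMWDec", "TMTD", "TMGA", "TMGCV")
    amp <- (unlist(m[ap]) / unlist(want[ap]) - 1) / 0.005
    tim <- (unlist(m[tp]) - unlist(want[tp])) / 0.005
    sum(amp^2, na.rm = TRUE) + sum(tim^2, na.rm = TRUE)
  }
  best <- adj
  best_score <- score(meas)
  for (it in seq_len(iterations)) {
    new_adj <- adj
    for (p in PARAM_NAMES)
      new_adj[[p]] <- adj[[p]] + damping * (want[[p]] - meas[[p]])
    new_adj <- clamp_targets(new_adj)
    new_meas <- measure(new_adj)
    if (is.null(new_meas)) break  # keep the last feasible adjustment
    adj <- new_adj
    meas <- new_meas
    sc <- score(meas)
    if (sc < best_score) {
      best <- adj
      best_score <- sc
    }
    if (sc < 2) break
  }
  best
}

#' Add Gaussian marker noise to a (clean) recording
#'
#' @param rec A [trial_recording()].
#' @param noise_sd Per-axis noise SD in mm (length 3).
#' @param seed Integer seed.
#' @return A new [trial_recording()] with perturbed marker positions.
#' @export
add_marker_noise <- function(rec, noise_sd = c(0.3, 0.2, 0.3), seed = 1L) {
  noise_sd <- rep_len(noise_sd, 3)
  n <- length(rec$t)
  with_seed(seed, {
    for (mname in MARKERS) {
      m <- rec[[mname]]
      for (j in 1:3) if (noise_sd[j] > 0)
        m[, j] <- m[, j] + stats::rnorm(n, 0, noise_sd[j])
      rec[[mname]] <- m
    }
  })
  rec
}

# ---- cohort generation -----------------------------------------------------

#' Calibration table of group x condition cell statistics
#'
#' Per-cell means and SDs of the eleven kinematic parameters for the two
#' groups and five imagery conditions; these are the default study-like
#' conditions the cohort generator reproduces. Units: MT s; MWV, MGCV m/s;
#' MWDec m/s^2; MTD, MGA mm; T* proportions.
#'
#' @return Data frame with columns `group`, `condition`, `parameter`, `mean`,
#'   `sd`.
#' @export
cohort_reference_stats <- function() {
  ctl_mean <- rbind(
    MT    = c(1.25, 1.25, 1.33, 1.24, 1.35),
    MWV   = c(0.66, 0.66, 0.64, 0.66, 0.61),
    MWDec = c(2.18, 2.11, 2.11, 2.16, 1.91),
    MTD   = c(22.25, 22.94, 22.12, 20.62, 20.77),
    MGA   = c(129.19, 129.46, 129.05, 129.86, 129.76),
    MGCV  = c(0.20, 0.19, 0.20, 0.21, 0.19),
    TMWV  = c(0.35, 0.37, 0.35, 0.37, 0.36),
    TMWDec = c(0.54, 0.57, 0.57, 0.56, 0.55),
    TMTD  = c(0.47, 0.45, 0.48, 0.46, 0.47),
    TMGA  = c(0.66, 0.66, 0.68, 0.67, 0.67),
    TMGCV = c(0.84, 0.83, 0.84, 0.84, 0.84))
  ctl_sd <- rbind(
    MT    = c(0.26, 0.29, 0.33, 0.25, 0.29),
    MWV   = c(0.13, 0.11, 0.13, 0.12, 0.11),
    MWDec = c(0.73, 0.62, 0.64, 0.72, 0.61),
    MTD   = c(7.93, 8.90, 7.07, 8.58, 7.42),
    MGA   = c(8.03, 8.50, 5.68, 7.78, 7.44),
    MGCV  = c(0.07, 0.06, 0.05, 0.08, 0.06),
    TMWV  = c(0.05, 0.06, 0.04, 0.05, 0.07),
    TMWDec = c(0.09, 0.10, 0.10, 0.09, 0.09),
    TMTD  = c(0.09, 0.10, 0.09, 0.07, 0.09),
    TMGA  = c(0.05, 0.04, 0.03, 0.04, 0.05),
    TMGCV = c(0.02, 0.03, 0.04, 0.02, 0.03))
  tc_mean <- rbind(
    MT    = c(1.92, 1.90, 1.88, 1.78, 2.03),
    MWV   = c(0.47, 0.49, 0.49, 0.48, 0.46),
    MWDec = c(1.22, 1.35, 1.33, 1.34, 1.20),
    MTD   = c(28.02, 33.21, 29.50, 38.68, 29.97),
    MGA   = c(126.90, 125.74, 126.50, 125.11, 127.17),
    MGCV  = c(0.11, 0.11, 0.13, 0.11, 0.10),
    TMWV  = c(0.35, 0.37, 0.38, 0.37, 0.35),
    TMWDec = c(0.51, 0.54, 0.57, 0.57, 0.53),
    TMTD  = c(0.42, 0.43, 0.42, 0.42, 0.43),
    TMGA  = c(0.70, 0.72, 0.71, 0.72, 0.70),
    TMGCV = c(0.86, 0.87, 0.87, 0.86, 0.87))
  tc_sd <- rbind(
    MT    = c(0.64, 0.58, 0.55, 0.53, 0.70),
    MWV   = c(0.13, 0.14, 0.13, 0.12, 0.14),
    MWDec = c(0.55, 0.63, 0.59, 0.53, 0.59),
    MTD   = c(10.66, 17.53, 16.77, 18.29, 12.86),
    MGA   = c(8.58, 7.28, 7.96, 8.14, 8.47),
    MGCV  = c(0.04, 0.03, 0.06, 0.06, 0.04),
    TMWV  = c(0.05, 0.06, 0.07, 0.05, 0.05),
    TMWDec = c(0.10, 0.14, 0.14, 0.13, 0.10),
    TMTD  = c(0.07, 0.07, 0.06, 0.05, 0.06),
    TMGA  = c(0.09, 0.08, 0.08, 0.08, 0.06),
    TMGCV = c(0.04, 0.04, 0.03, 0.04, 0.04))
  build <- function(g, mm, ss) {
    do.call(rbind, lapply(seq_along(CONDITIONS), function(j)
      data.frame(group = g, condition = CONDITIONS[j],
                 parameter = rownames(mm), mean = mm[, j], sd = ss[, j],
                 row.names = NULL)))
  }
  rbind(build("Control", ctl_mean, ctl_sd), build("TC", tc_mean, tc_sd))
}

#' Flatten a cell-statistics table to a null (no-effect) version
#'
#' Replaces every parameter's cell means with its grand mean and every SD
#' with the mean SD, preserving realistic scales while removing all group and
#' condition effects — the configuration used for type-I-error calibration.
#'
#' @param cells Cell statistics, default [cohort_reference_stats()].
#' @return Cell-statistics data frame of the same shape.
#' @export
null_cell_stats <- function(cells = cohort_reference_stats()) {
  for (p in unique(cells$parameter)) {
    sel <- cells$parameter == p
    cells$mean[sel] <- mean(cells$mean[sel])
    cells$sd[sel] <- mean(cells$sd[sel])
  }
  cells
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 15 practitioners and 14 controls
#' (one of the 30 volunteers excluded), ten trials per condition, cell means
#' and SDs from [cohort_reference_stats()], and a years-of-practice
#' distribution of one 40-year master, four ~10-year instructors and ten
#' ~6-year apprentices.
#'
#' @param n_tc,n_control Participants per group.
#' @param trials_per_cell Trials per participant and condition (study: 10).
#' @param cell_stats Cell statistics table (group, condition, parameter,
#'   mean, sd).
#' @param intercept_share Share of the between-participant variance carried
#'   by a participant-level random intercept common to all conditions
#'   (default 0.5).
#' @param trial_sd_frac Trial-to-trial SD within a participant-condition
#'   cell, as a fraction of the cell SD (default 0.5).
#' @param years_tc Optional vector of years of practice for the TC group
#'   (length `n_tc`).
#' @param noise_sd,fs Marker noise (mm per axis) and sampling rate passed to
#'   the trial generator.
#' @param seed Master seed; all trial seeds derive from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_tc = 15, n_control = 14, trials_per_cell = 10,
                        cell_stats = cohort_reference_stats(),
                        intercept_share = 0.5, trial_sd_frac = 0.5,
                        years_tc = NULL, noise_sd = c(0.3, 0.2, 0.3),
                        fs = 140, seed = 1L) {
  if (n_tc < 1 || n_control < 0 || trials_per_cell < 1)
    rk_abort("cohort sizes must be positive", "config")
  if (any(cell_stats$sd < 0)) rk_abort("cell SDs must be non-negative",
                                       "config")
  structure(list(n_tc = n_tc, n_control = n_control,
                 trials_per_cell = trials_per_cell, cell_stats = cell_stats,
                 intercept_share = intercept_share,
                 trial_sd_frac = trial_sd_frac, years_tc = years_tc,
                 noise_sd = rep_len(noise_sd, 3), fs = fs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

default_years_tc <- function(n) {
  base <- c(40, rep(10, 4), rep(6, 10))
  if (n <= length(base)) base[seq_len(n)] else
    c(base, rep(6, n - length(base)))
}

#' Draw cohort metadata and per-trial parameter targets
#'
#' Participant-by-condition parameter targets are drawn around the cell means
#' with the cell SD split between a participant random intercept
#' (`intercept_share`) and a condition-specific deviate; trial targets add
#' `trial_sd_frac * sd` of independent trial noise. This parameter-level
#' stage is what the statistical calibration simulations run on; the marker
#' renderer ([gen_cohort()]) solves each trial target into a full recording.
#'
#' @param cspec A [cohort_spec()].
#' @return List: `meta` (participant_id, group, years_practice), `trials`
#'   (participant, group, condition, trial + the eleven target parameters).
#' @export
gen_cohort_params <- function(cspec) {
  cs <- cspec$cell_stats
  with_seed(cspec$seed, {
    meta <- data.frame(
      participant_id = c(sprintf("TC%02d", seq_len(cspec$n_tc)),
                         sprintf("CT%02d", seq_len(cspec$n_control))),
      group = c(rep("TC", cspec$n_tc), rep("Control", cspec$n_control)),
      years_practice = c(cspec$years_tc %||% default_years_tc(cspec$n_tc),
                         rep(0, cspec$n_control)))
    np <- length(PARAM_NAMES)
    tpc <- cspec$trials_per_cell
    grid <- expand.grid(trial = seq_len(tpc), condition = CONDITIONS,
                        participant = meta$participant_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[c("participant", "condition", "trial")]
    grid$group <- meta$group[match(grid$participant, meta$participant_id)]
    key <- paste(cs$group, cs$condition, cs$parameter)
    vals <- matrix(NA_real_, nrow(grid), np,
                   dimnames = list(NULL, PARAM_NAMES))
    for (i in seq_len(nrow(meta))) {
      bi <- stats::rnorm(np)
      for (cc in CONDITIONS) {
        mu <- cs$mean[match(paste(meta$group[i], cc, PARAM_NAMES), key)]
        sdv <- cs$sd[match(paste(meta$group[i], cc, PARAM_NAMES), key)]
        zc <- stats::rnorm(np)
        pc_mean <- mu + sdv * (sqrt(cspec$intercept_share) * bi +
                               sqrt(1 - cspec$intercept_share) * zc)
        sel <- which(grid$participant == meta$participant_id[i] &
                     grid$condition == cc)
        vals[sel, ] <- rep(pc_mean, each = tpc) +
          cspec$trial_sd_frac * rep(sdv, each = tpc) *
            stats::rnorm(tpc * np)
      }
    }
    trials <- cbind(grid[c("participant", "group", "condition", "trial")],
                    as.data.frame(vals))
    list(meta = meta, trials = trials)
  })
}

# Nudge a drawn target vector into the generator's feasible region.
clamp_targets <- function(tv) {
  tv$MT <- max(tv$MT, 0.75)
  tv$MWV <- max(tv$MWV, 0.08)
  tv$MWDec <- max(tv$MWDec, 0.15)
  tv$TMWV <- min(max(tv$TMWV, 0.08), 0.70)
  tv$TMWDec <- min(max(tv$TMWDec, tv$TMWV + 0.06), 0.95)
  tv$MGA <- min(max(tv$MGA, APERTURE_CONTACT + 10), 200)
  tv$TMGA <- min(max(tv$TMGA, 0.30), 0.90)
  tv$TMGCV <- min(max(tv$TMGCV, tv$TMGA + 0.04), 0.97)
  tv$MGCV <- max(tv$MGCV, 0.03)
  tv$TMTD <- min(max(tv$TMTD, 0.10), min(0.65, tv$TMWDec))
  tv
}

#' Generate a full synthetic cohort of marker recordings
#'
#' Draws targets with [gen_cohort_params()] and solves each trial's targets
#' into a clean trajectory plus marker noise. Trials whose drawn targets are
#' infeasible (e.g. closing-velocity targets inconsistent with the aperture
#' amplitude) are redrawn around the same participant-condition mean, up to
#' `max_attempts` times.
#'
#' @param cspec A [cohort_spec()].
#' @param max_attempts Redraws allowed per trial (default 100).
#' @param calibrate Nudge each trial's targets so the noise-free pipeline
#'   measurement equals the drawn target values (default `TRUE`; see
#'   [gen_reach_trial()]).
#' @return List: `recordings` (list of [trial_recording()]), `meta`,
#'   `targets` (drawn per-trial targets), `ground_truth` (noise-free pipeline
#'   measurement of each clean trial, one row per trial).
#' @export
gen_cohort <- function(cspec, max_attempts = 100, calibrate = TRUE) {
  pars <- gen_cohort_params(cspec)
  trials <- pars$trials
  recordings <- vector("list", nrow(trials))
  gt <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    tv <- clamp_targets(as.list(row[PARAM_NAMES]))
    tseed <- derive_seed(cspec$seed, i)
    trial <- NULL
    for (att in seq_len(max_attempts)) {
      trial <- tryCatch({
        tvc <- if (calibrate) calibrate_targets(tv, fs = cspec$fs) else tv
        sp <- trial_spec(fs = cspec$fs, noise_sd = cspec$noise_sd,
                         seed = tseed, targets = tvc)
        gen_reach_trial(sp, row$participant, row$group, row$condition,
                        row$trial)
      }, reachkin_spec_error = function(e) NULL)
      if (!is.null(trial)) break
      # redraw around the drawn targets, pulling increasingly toward the
      # cell reference means so persistent infeasibilities resolve
      jseed <- derive_seed(tseed, att)
      cell <- cspec$cell_stats[cspec$cell_stats$group == row$group &
                               cspec$cell_stats$condition == row$condition, ]
      mu <- as.list(stats::setNames(cell$mean, cell$parameter)[PARAM_NAMES])
      pull <- min(0.08 * att, 0.9)
      jit_sd <- min(0.02 * att, 0.10)
      tv <- with_seed(jseed, {
        base <- as.list(row[PARAM_NAMES])
        jit <- mapply(function(v, m)
          ((1 - pull) * v + pull * m) * (1 + stats::rnorm(1, 0, jit_sd)),
          base, mu, SIMPLIFY = FALSE)
        clamp_targets(jit)
      })
    }
    if (is.null(trial))
      rk_abort(sprintf("no feasible trial after %d attempts (%s/%s/%d)",
                       max_attempts, row$participant, row$condition,
                       row$trial), "infeasible")
    trials[i, PARAM_NAMES] <- unlist(tv)
    recordings[[i]] <- trial$recording
    gt[[i]] <- cbind(row[c("participant", "group", "condition", "trial")],
                     trial$ground_truth)
  }
  list(recordings = recordings, meta = pars$meta, targets = trials,
       ground_truth = do.call(rbind, gt))
}

# ---- CPT generation --------------------------------------------------------

#' Simulate one CPT session under equal-variance signal detection
#'
#' Hit and false-alarm counts are binomial draws with rates
#' `pnorm(true_dprime - criterion)` and `pnorm(-criterion)`.
#'
#' @param true_dprime True sensitivity.
#' @param criterion Absolute response criterion (default 0.5).
#' @param n_signal,n_noise Numbers of critical and non-critical trials
#'   (defaults 30 and 570: 600 one-second trials over 10 minutes at a 5%
#'   critical-stimulus rate).
#' @param seed Integer seed.
#' @return One-row data frame: `n_signal`, `n_noise`, `hits`, `false_alarms`.
#' @export
gen_cpt_session <- function(true_dprime, criterion = 0.5, n_signal = 30,
                            n_noise = 570, seed = 1L) {
  if (n_signal <= 0 || n_noise <= 0)
    rk_abort("trial counts must be positive", "spec")
  with_seed(seed, data.frame(
    n_signal = n_signal, n_noise = n_noise,
    hits = stats::rbinom(1, n_signal, stats::pnorm(true_dprime - criterion)),
    false_alarms = stats::rbinom(1, n_noise, stats::pnorm(-criterion))))
}

#' Simulate a two-group CPT cohort
#'
#' Participant-level true sensitivities are drawn from group-specific normal
#' distributions (defaults: practitioners 0.98 +- 0.82, controls 0.01 +-
#' 1.17), then each participant's session is sampled and scored with the
#' loglinear d'.
#'
#' @param n_per_group Participants per group (default 13).
#' @param mean_dprime,sd_dprime Named numeric vectors (`TC`, `Control`).
#' @param criterion,n_signal,n_noise Session settings, see
#'   [gen_cpt_session()].
#' @param seed Master seed.
#' @return Data frame: `participant_id`, `group`, counts, `true_dprime`,
#'   `dprime`.
#' @export
gen_cpt_cohort <- function(n_per_group = 13,
                           mean_dprime = c(TC = 0.98, Control = 0.01),
                           sd_dprime = c(TC = 0.82, Control = 1.17),
                           criterion = 0.5, n_signal = 30, n_noise = 570,
                           seed = 1L) {
  with_seed(seed, {
    out <- list()
    for (g in GROUPS) {
      for (i in seq_len(n_per_group)) {
        td <- stats::rnorm(1, mean_dprime[[g]], sd_dprime[[g]])
        sess <- gen_cpt_session(td, criterion, n_signal, n_noise,
                                seed = derive_seed(seed, length(out) + 1))
        out[[length(out) + 1]] <- cbind(
          data.frame(participant_id = sprintf("%s%02d", g, i), group = g,
                     true_dprime = td), sess)
      }
    }
    out <- do.call(rbind, out)
    out$dprime <- loglinear_dprime(out$hits, out$false_alarms, out$n_signal,
                                   out$n_noise)
    out
  })
}

#' Synthetic Range-versus-practice data with a known standardized slope
#'
#' Generates practitioner Range values linearly related to years of practice
#' with true standardized slope `beta`, for regression-recovery checks.
#'
#' @param beta True standardized slope in (-1, 1).
#' @param years Years-of-practice vector (default: the study-like
#'   distribution for n = 15).
#' @param mu,sigma Location and scale of the Range values.
#' @param seed Integer seed.
#' @return Data frame: `participant_id`, `group`, `years_practice`,
#'   `range_value`.
#' @export
gen_range_vs_years <- function(beta = 0.92, years = default_years_tc(15),
                               mu = 0.12, sigma = 0.03, seed = 1L) {
  if (abs(beta) >= 1) rk_abort("standardized slope must lie in (-1, 1)",
                               "spec")
  with_seed(seed, {
    zx <- as.numeric(scale(years))
    y <- beta * zx + sqrt(1 - beta^2) * stats::rnorm(length(years))
    data.frame(participant_id = sprintf("TC%02d", seq_along(years)),
               group = "TC", years_practice = years,
               range_value = mu + sigma * y)
  })
}
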