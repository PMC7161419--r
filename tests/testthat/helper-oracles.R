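# Independent brute-force oracles used to validate the detectors, plus small
# fixture builders. These deliberately avoid the package's internal scan
# logic (plain loops over all candidate indices).

oracle_onset <- function(speed, fs, threshold = 5, sustain = 0.5) {
  k <- as.integer(round(sustain * fs))
  n <- length(speed)
  for (i in seq_len(n - k)) {
    if (all(speed[i:(i + k)] > threshold)) return(i)
  }
  NA_integer_
}

oracle_offset <- function(aperture_vel, after_idx, threshold = 5) {
  closing <- -aperture_vel
  n <- length(closing)
  exceeded <- FALSE
  for (i in (after_idx + 1):n) {
    if (!exceeded && closing[i] > threshold) exceeded <- TRUE
    else if (exceeded && closing[i] <= threshold) return(i)
  }
  NA_integer_
}

# A stationary recording with all markers fixed; optionally perturbed.
make_static_recording <- function(n = 300, fs = 140, noise = 0, seed = 1) {
  t <- (seq_len(n) - 1) / fs
  base <- function(center) {
    m <- matrix(rep(center, each = n), ncol = 3)
    if (noise > 0) m <- m + matrix(stats::rnorm(3 * n, 0, noise), ncol = 3)
    m
  }
  if (noise > 0) set.seed(seed)
  trial_recording("S01", "TC", "A", 1L, fs, t,
                  base(c(0, 0, 0)), base(c(60, 40, -10)), base(c(60, 40, 10)))
}

# Default study-like cell targets (control group, still-water condition).
control_a_targets <- function() {
  list(MT = 1.25, MWV = 0.66, MWDec = 2.18, MTD = 22.25, MGA = 129.19,
       MGCV = 0.20, TMWV = 0.35, TMWDec = 0.54, TMTD = 0.47, TMGA = 0.66,
       TMGCV = 0.84)
}

# Tiny cohort spec for fast end-to-end tests.
tiny_cohort_spec <- function(seed = 7, sd_scale = 1, trials = 1,
                             n_tc = 2, n_control = 2) {
  cs <- cohort_reference_stats()
  cs$sd <- cs$sd * sd_scale
  cohort_spec(n_tc = n_tc, n_control = n_control, trials_per_cell = trials,
              cell_stats = cs, seed = seed)
}
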