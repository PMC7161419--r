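# Movement segmentation and parameter extraction, validated against
# brute-force oracles and closed-form geometry.

test_that("onset detector follows the sustained-threshold rule", {
  fs <- 140
  expect_error(detect_movement_onset(rep(0, 400), fs),
               class = "reachkin_no_movement_error")

  # immediate crossing that lasts: onset at the first sample
  expect_equal(detect_movement_onset(rep(10, 280), fs), 1L)

  # crossing at 40 that dips at 60, sustained re-crossing at 100
  sp <- rep(0, 400)
  sp[40:59] <- 10
  sp[100:400] <- 10
  expect_equal(detect_movement_onset(sp, fs), 100L)
  expect_equal(oracle_onset(sp, fs), 100L)
})

test_that("offset detector returns the end of the first closing pulse", {
  fs <- 140
  # aperture constant after the maximum: no closing at all
  expect_error(detect_grip_offset(rep(0, 300), fs, after_idx = 100),
               class = "reachkin_no_contact_error")

  # triangular closing pulse 0 -> 50 -> 0 mm/s
  av <- rep(0, 300)
  av[101:150] <- -seq(2, 100, by = 2)
  av[151:200] <- -seq(98, 0, by = -2)
  k <- detect_grip_offset(av, fs, after_idx = 100)
  expect_equal(k, oracle_offset(av, 100))
  expect_true(-av[k] <= 5 && -av[k - 1] > 5)

  # two pulses: offset at the end of the first one that exceeds threshold
  av2 <- av
  av2[221:260] <- -30
  expect_equal(detect_grip_offset(av2, fs, 100), k)
})

test_that("detectors agree with the brute-force oracle on random signals", {
  set.seed(1234)
  fs <- 140
  for (rep in 1:200) {
    n <- sample(150:400, 1)
    # random piecewise-constant speed with jitter
    nseg <- sample(3:8, 1)
    lv <- stats::runif(nseg, 0, 20)
    sp <- rep(lv, length.out = n, each = ceiling(n / nseg))[1:n] +
      stats::runif(n, -1, 1)
    on_pkg <- tryCatch(detect_movement_onset(sp, fs),
                       reachkin_no_movement_error = function(e) NA_integer_)
    expect_identical(on_pkg, oracle_onset(sp, fs))

    av <- -(rep(stats::runif(nseg, 0, 30), length.out = n,
                each = ceiling(n / nseg))[1:n] + stats::runif(n, -1, 1))
    after <- sample(seq_len(n %/% 2), 1)
    off_pkg <- tryCatch(detect_grip_offset(av, fs, after),
                        reachkin_no_contact_error = function(e) NA_integer_)
    expect_identical(off_pkg, oracle_offset(av, after))
  }
})

test_that("segmentation recovers the movement time of synthetic trials", {
  tr <- gen_reach_trial(trial_spec(mt = 1.30, noise_sd = c(0.3, 0.2, 0.3),
                                   seed = 21))
  seg <- segment_movement(build_profile(tr$recording))
  expect_lt(abs(seg$movement_time - 1.30), 0.05)

  # no reach at all
  expect_error(segment_movement(build_profile(make_static_recording(400))),
               class = "reachkin_no_movement_error")
})

test_that("min-jerk closed forms are recovered on the exact movement interval", {
  tr <- gen_reach_trial(trial_spec(mt = 1.3, distance = 350,
                                   noise_sd = c(0, 0, 0)))
  prof <- build_profile(tr$recording)
  seg <- movement_segment(tr$truth_times$nominal_start_idx,
                          tr$truth_times$nominal_end_idx, 140)
  pars <- extract_parameters(prof, seg)
  expect_equal(pars$TMWV, 0.5, tolerance = 0.005)
  expect_equal(pars$MWV * 1000, 1.875 * 350 / 1.3, tolerance = 0.005 * 505)
  # analytic deceleration-peak time (root of 2 - 12 tau + 12 tau^2 in (0.5, 1))
  expect_lt(abs(pars$TMWDec - (1 + 1 / sqrt(3)) / 2), 1 / (1.3 * 140) + 1e-9)
})

test_that("trajectory deviation: collinear, circular-arc and signed cases", {
  fs <- 140
  n <- 141
  t <- (seq_len(n) - 1) / fs
  # straight path
  straight <- cbind(seq(0, 350, length.out = n), 0, 0)
  seg <- movement_segment(1L, n, fs)
  expect_equal(trajectory_deviation(straight, seg)$MTD, 0)

  # planar circular arc: chord 350 mm, sagitta 25 mm, constant speed
  chord <- 350
  sag <- 25
  R <- (chord^2 / 4 + sag^2) / (2 * sag)
  half <- asin(chord / (2 * R))
  th <- seq(-half, half, length.out = n)
  arc <- cbind(R * sin(th) + chord / 2, 0, R * cos(th) - (R - sag))
  dev <- trajectory_deviation(arc, seg)
  expect_equal(abs(dev$MTD), 25, tolerance = 0.01)
  expect_equal(dev$TMTD, 0.5, tolerance = 0.01)
  # bump on +z: rightward positive under the cross(d, up) convention
  expect_gt(dev$MTD, 0)
  # reflection flips the sign
  refl <- arc
  refl[, 3] <- -refl[, 3]
  expect_equal(trajectory_deviation(refl, seg)$MTD, -dev$MTD,
               tolerance = 1e-9)

  expect_error(trajectory_deviation(straight * 0, seg),
               class = "reachkin_degenerate_line_error")
})

test_that("an injected rightward deviation is recovered in noisy TC-like trials", {
  tg <- list(MT = 1.78, MWV = 0.48, MWDec = 1.34, MTD = 32, MGA = 125.11,
             MGCV = 0.11, TMWV = 0.37, TMWDec = 0.57, TMTD = 0.42,
             TMGA = 0.72, TMGCV = 0.86)
  vals <- sapply(1:20, function(k) {
    tr <- gen_reach_trial(trial_spec(seed = k, targets = tg))
    extract_trial(tr$recording)$MTD
  })
  expect_gt(mean(vals), 0)
  expect_lt(abs(mean(vals) - 32), 3)
})

test_that("extraction is invariant under translation and vertical-axis rotation,
           and peak-time ordering holds across varied trials", {
  tr <- gen_reach_trial(trial_spec(seed = 31, noise_sd = c(0.3, 0.2, 0.3)))
  rec <- tr$recording
  base <- extract_trial(rec)

  rot <- function(m, ang) {
    R <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3)
    m %*% t(R)
  }
  moved <- rec
  for (m in c("wrist", "thumb", "index"))
    moved[[m]] <- sweep(rot(rec[[m]], 0.7), 2, c(100, 50, -30), "+")
  rotated <- extract_trial(moved)
  for (p in c("MT", "MWV", "MWDec", "MGA", "MGCV", "TMWV", "TMWDec",
              "TMGA", "TMGCV"))
    expect_equal(rotated[[p]], base[[p]], tolerance = 1e-4)
  expect_equal(rotated$MTD, base$MTD, tolerance = 0.01)

  # ordering invariants on a varied sample of noisy target-driven trials
  set.seed(88)
  cs <- tiny_cohort_spec(seed = 88, trials = 1, n_tc = 3, n_control = 3)
  pars <- gen_cohort_params(cs)$trials
  for (i in seq_len(min(nrow(pars), 25))) {
    tv <- reachkin:::clamp_targets(as.list(pars[i, PARAM_NAMES]))
    row <- tryCatch({
      tr <- gen_reach_trial(trial_spec(seed = i, targets = tv))
      extract_trial(tr$recording)
    }, reachkin_spec_error = function(e) NULL)
    if (is.null(row)) next
    expect_true(row$TMWV < row$TMWDec)
    expect_true(row$TMGA < row$TMGCV)
    expect_true(all(c(row$TMWV, row$TMWDec, row$TMGA, row$TMGCV) >= 0 &
                    c(row$TMWV, row$TMWDec, row$TMGA, row$TMGCV) <= 1))
  }
})
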