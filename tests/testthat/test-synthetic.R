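# Generator behaviour: determinism, closed forms, ground-truth round trips,
# cohort calibration.

test_that("trial generation is deterministic for a fixed seed", {
  sp <- trial_spec(seed = 42)
  a <- gen_reach_trial(sp)
  b <- gen_reach_trial(sp)
  expect_identical(a$recording$wrist, b$recording$wrist)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- gen_reach_trial(trial_spec(seed = 43))
  expect_false(identical(a$recording$wrist, c$recording$wrist))
})

test_that("spec invariants are enforced", {
  expect_error(trial_spec(mt = 0.5), class = "reachkin_spec_error")
  expect_error(trial_spec(mga = 80), class = "reachkin_spec_error")
  expect_error(trial_spec(tmga = 0.9, tmgcv = 0.8),
               class = "reachkin_spec_error")
})

test_that("noiseless min-jerk trials hit their closed forms", {
  tr <- gen_reach_trial(trial_spec(mt = 1.3, distance = 350,
                                   noise_sd = c(0, 0, 0)))
  # extracted peak speed within 0.5% of 1.875 * D / MT
  ext <- extract_trial(tr$recording)
  expect_lt(abs(ext$MWV * 1000 / (1.875 * 350 / 1.3) - 1), 0.005)
  # zero injected deviation: extracted deviation at discretisation level
  expect_lt(abs(ext$MTD), 0.5)
  # analytic profile truth records the min-jerk values
  expect_equal(tr$profile_truth$MWV * 1000, 1.875 * 350 / 1.3,
               tolerance = 1e-9)
  expect_equal(tr$profile_truth$MWDec * 1000, 5.7735027 * 350 / 1.3^2,
               tolerance = 1e-6)
})

test_that("noise-free extraction equals the exported ground truth", {
  tg <- control_a_targets()
  tr <- gen_reach_trial(trial_spec(noise_sd = c(0, 0, 0), targets = tg))
  ext <- extract_trial(tr$recording)
  for (p in PARAM_NAMES)
    expect_equal(ext[[p]], tr$ground_truth[[p]], tolerance = 1e-12)
})

test_that("a zero-variance, noise-free cohort reproduces its cell targets", {
  cs <- tiny_cohort_spec(seed = 5, sd_scale = 0, trials = 1,
                         n_tc = 1, n_control = 1)
  cs$noise_sd <- c(0, 0, 0)
  cohort <- gen_cohort(cs)
  ref <- cohort_reference_stats()
  tab <- do.call(rbind, lapply(cohort$recordings, extract_trial))
  for (i in seq_len(nrow(tab))) {
    cell <- ref[ref$group == tab$group[i] & ref$condition == tab$condition[i], ]
    want <- stats::setNames(cell$mean, cell$parameter)
    for (p in c("MWV", "MWDec", "MGA", "MGCV", "MTD"))
      expect_lt(abs(tab[[p]][i] / want[[p]] - 1), 0.025)
    for (p in c("MT", "TMWV", "TMWDec", "TMTD", "TMGA", "TMGCV"))
      expect_lt(abs(tab[[p]][i] - want[[p]]), 0.045)
  }
  # ground-truth table matches the extraction (noise-free measurement)
  expect_equal(tab$MWV, cohort$ground_truth$MWV, tolerance = 1e-9)
})

test_that("cohort generation is reproducible and carries years of practice", {
  cs <- tiny_cohort_spec(seed = 9, trials = 1)
  a <- gen_cohort(cs)
  b <- gen_cohort(cs)
  expect_identical(a$recordings[[3]]$wrist, b$recordings[[3]]$wrist)
  expect_equal(a$meta$years_practice[a$meta$group == "Control"], c(0, 0))
  expect_true(all(a$meta$years_practice[a$meta$group == "TC"] > 0))
  expect_equal(length(a$recordings), 2 * 2 * 5 * 1)
})

test_that("parameter-level cohort draws have the requested moment structure", {
  cs <- cohort_spec(n_tc = 60, n_control = 60, trials_per_cell = 2, seed = 3)
  pars <- gen_cohort_params(cs)
  ref <- cohort_reference_stats()
  pm <- participant_condition_means(pars$trials, "MT")
  for (g in c("TC", "Control")) {
    for (cc in c("A", "E")) {
      cell <- ref[ref$group == g & ref$condition == cc &
                  ref$parameter == "MT", ]
      v <- pm$value[pm$group == g & pm$condition == cc]
      expect_lt(abs(mean(v) - cell$mean), 4 * cell$sd / sqrt(60))
      expect_lt(abs(stats::sd(v) - sqrt(cell$sd^2 + 0.25 * cell$sd^2 / 2)),
                0.3 * cell$sd)
    }
  }
})

test_that("CPT cohort simulation recovers the group separation", {
  cpt <- gen_cpt_cohort(n_per_group = 40, seed = 11)
  res <- compare_dprime(cpt)
  expect_gt(res$mean_tc, res$mean_control)
  expect_equal(res$mean_tc - res$mean_control, 0.97, tolerance = 0.45)
})

test_that("range-vs-years helper produces the requested standardized slope", {
  d <- gen_range_vs_years(beta = 0.92, seed = 2)
  expect_equal(nrow(d), 15)
  expect_true(all(d$group == "TC"))
  b <- stats::cor(d$years_practice, d$range_value)
  expect_lt(abs(b - 0.92), 0.2)
})
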