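# Mixed models, planned contrast, regressions, d' comparison and summaries.

# Deterministic participant x condition x trial table with optional additive
# effects: value = base + group_shift (TC) + e_shift (session E) + noise.
make_tidy <- function(n_tc = 6, n_ct = 6, trials = 2, base = 1,
                      group_shift = 0, e_shift = 0, sd = 0, seed = 1,
                      participant_sd = 0) {
  set.seed(seed)
  rows <- list()
  for (g in c("TC", "Control")) {
    n <- if (g == "TC") n_tc else n_ct
    for (i in seq_len(n)) {
      pid <- sprintf("%s%02d", g, i)
      b <- stats::rnorm(1, 0, participant_sd)
      for (cc in c("A", "B", "C", "D", "E")) {
        for (k in seq_len(trials)) {
          v <- base + b + (g == "TC") * group_shift + (cc == "E") * e_shift +
            stats::rnorm(1, 0, sd)
          row <- data.frame(participant = pid, group = g, condition = cc,
                            trial = k)
          for (p in PARAM_NAMES) row[[p]] <- v
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("noise-free additive group shift is recovered exactly", {
  tidy <- make_tidy(group_shift = 0.6)
  fit <- suppressWarnings(fit_condition_group_model(tidy, "MT"))
  # estimated group difference within every session equals the injected shift
  expect_equal(fit$posthoc$estimate, rep(0.6, 5), tolerance = 1e-8)
  expect_equal(fit$anova$df1[fit$anova$effect == "group"], 1)
})

test_that("mixed model degrees of freedom sit on the participant scale", {
  tidy <- make_tidy(n_tc = 15, n_ct = 14, trials = 1, sd = 0.05,
                    participant_sd = 0.3, group_shift = 0.5, seed = 3)
  fit <- fit_condition_group_model(tidy, "MGCV")
  an <- fit$anova
  expect_equal(an$df2[an$effect == "group"], 27, tolerance = 0.2)
  expect_equal(an$df2[an$effect == "condition"], 108, tolerance = 0.5)
  expect_lt(an$p[an$effect == "group"], 0.001)
})

test_that("the Session-E planned contrast estimates E minus the mean of A-D", {
  tidy <- make_tidy(e_shift = -0.05, sd = 0, participant_sd = 0.2, seed = 2)
  fit <- suppressWarnings(fit_condition_group_model(tidy, "MWV"))
  expect_equal(fit$contrast_E$estimate, -0.05, tolerance = 1e-8)

  flat <- make_tidy(sd = 0.001, participant_sd = 0.2, seed = 4)
  fit0 <- suppressWarnings(fit_condition_group_model(flat, "MWV"))
  expect_equal(fit0$contrast_E$estimate, 0, tolerance = 0.01)
  expect_gt(fit0$contrast_E$p, 0.1)
})

test_that("model preconditions are enforced", {
  tidy <- make_tidy()
  expect_error(fit_condition_group_model(tidy[tidy$group == "TC", ], "MT"),
               class = "reachkin_design_error")
  expect_error(fit_condition_group_model(tidy[tidy$condition != "E", ], "MT"),
               class = "reachkin_design_error")
})

test_that("range-on-years regression: perfect fit, identity beta^2 = R^2,
           and the null distribution of R^2", {
  years <- c(40, rep(10, 4), rep(6, 10))
  meta <- data.frame(participant_id = sprintf("TC%02d", 1:15), group = "TC",
                     years_practice = years)
  ranges <- data.frame(participant_id = meta$participant_id,
                       group = "TC", parameter = "TMGCV",
                       range_value = 0.01 + 0.002 * years)
  fit <- suppressWarnings(regress_range_on_years(ranges, meta, "TMGCV"))
  expect_equal(fit$beta, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # beta^2 == R^2 for any single-predictor fit
  set.seed(6)
  for (k in 1:20) {
    ranges$range_value <- stats::rnorm(15)
    f <- regress_range_on_years(ranges, meta, "TMGCV")
    expect_equal(f$beta^2, f$r_squared, tolerance = 1e-10)
  }

  # under independence, E[R^2] = 1 / (n - 1)
  set.seed(7)
  r2 <- replicate(400, {
    ranges$range_value <- stats::rnorm(15)
    regress_range_on_years(ranges, meta, "TMGCV")$r_squared
  })
  expect_lt(abs(mean(r2) - 1 / 14), 0.01)

  ranges$range_value <- 1:15
  meta0 <- meta
  meta0$years_practice <- 5
  expect_error(regress_range_on_years(ranges, meta0, "TMGCV"),
               class = "reachkin_degenerate_design_error")
})

test_that("d-prime group comparison: null cases and pooled-SD effect size", {
  dp <- data.frame(group = rep(c("TC", "Control"), each = 4),
                   dprime = c(0, 1, 0, 1, 0, 1, 0, 1))
  res <- compare_dprime(dp)
  expect_equal(res$t, 0)
  expect_equal(res$cohens_d, 0)

  # group summaries matching the reported magnitudes: d from pooled SD
  set.seed(8)
  x <- stats::rnorm(13)
  y <- stats::rnorm(13)
  x <- (x - mean(x)) / stats::sd(x) * 0.82 + 0.98
  y <- (y - mean(y)) / stats::sd(y) * 1.17 + 0.01
  res2 <- compare_dprime(data.frame(group = rep(c("TC", "Control"), each = 13),
                                    dprime = c(x, y)))
  expect_equal(res2$cohens_d, 0.97 / sqrt((0.82^2 + 1.17^2) / 2),
               tolerance = 1e-9)
  expect_equal(res2$cohens_d, 0.96, tolerance = 0.005)
  expect_equal(res2$df, 24)

  dp0 <- data.frame(group = rep(c("TC", "Control"), each = 3), dprime = 1)
  expect_error(compare_dprime(dp0), class = "reachkin_degenerate_error")
})

test_that("cell summary and equal-weight marginals reproduce printed values", {
  # marginals straight from the calibration cell means
  marg <- cell_marginals(cohort_reference_stats())
  get <- function(g, p) round(marg$mean[marg$group == g & marg$parameter == p], 2)
  expect_equal(get("TC", "MT"), 1.90)
  expect_equal(get("Control", "MWV"), 0.65)
  expect_equal(get("TC", "MGCV"), 0.11)
  expect_equal(get("Control", "MGCV"), 0.20)

  # summary over a tidy table: one participant, one trial -> flagged SD
  tidy <- make_tidy(n_tc = 1, n_ct = 1, trials = 1, base = 2)
  summ <- group_condition_summary(tidy, parameters = "MT")
  expect_true(all(summ$cells$flag == "single_participant"))
  expect_true(all(is.na(summ$cells$sd)))
  expect_equal(unique(summ$cells$mean), 2)

  expect_error(group_condition_summary(tidy[tidy$condition != "C", ],
                                       parameters = "MT"),
               class = "reachkin_missing_cell_error")
})
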