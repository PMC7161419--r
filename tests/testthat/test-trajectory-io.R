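test_that("trial CSV round-trips and reports its duration from n/fs", {
  sp <- trial_spec(mt = 1.3, noise_sd = c(0.3, 0.2, 0.3), seed = 11)
  rec <- gen_reach_trial(sp, "P03", "Control", "B", 4L)$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, path)
  back <- read_trial_csv(path)

  expect_equal(back$participant_id, "P03")
  expect_equal(back$group, "Control")
  expect_equal(back$condition, "B")
  expect_equal(back$trial_index, 4L)
  expect_equal(back$fs, 140)
  # written at 1e-6 precision: numeric fields round-trip to that exactly
  for (m in c("wrist", "thumb", "index"))
    expect_equal(back[[m]], round(rec[[m]], 6), tolerance = 1e-12)
  expect_equal(recording_duration(back), length(rec$t) / rec$fs)

  # a 280-sample recording at 140 Hz lasts exactly 2 s
  rec2 <- make_static_recording(n = 280, fs = 140)
  expect_equal(recording_duration(rec2), 2.0)
})

test_that("malformed trial files raise classed errors", {
  sp <- trial_spec(seed = 2)
  rec <- gen_reach_trial(sp)$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, path)

  lines <- readLines(path)
  # drop the thumb_z column
  no_col <- sapply(strsplit(lines[-(1:5)], ","), function(x)
    paste(x[-9], collapse = ","))
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1:5], no_col), p1)
  expect_error(read_trial_csv(p1), class = "reachkin_format_error")

  # non-uniform sampling beyond tolerance
  df <- utils::read.csv(text = lines[-(1:5)])
  df$time[10] <- df$time[10] + 0.002
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1:5], paste(names(df), collapse = ","),
               apply(df, 1, paste, collapse = ",")), p2)
  expect_error(read_trial_csv(p2), class = "reachkin_sampling_error")

  # NaN run -> gap error naming the sample range
  df2 <- utils::read.csv(text = lines[-(1:5)])
  df2$wrist_x[20:22] <- NA
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1:5], paste(names(df2), collapse = ","),
               apply(df2, 1, paste, collapse = ",")), p3)
  err <- expect_error(read_trial_csv(p3), class = "reachkin_gap_error")
  expect_match(conditionMessage(err), "20-22")
})

test_that("validate_recording flags spikes, gaps and short recordings", {
  rec <- gen_reach_trial(trial_spec(seed = 3))$recording
  expect_equal(nrow(validate_recording(rec)), 0)

  spiked <- rec
  spiked$wrist[100, 1] <- spiked$wrist[100, 1] + 200
  iss <- validate_recording(spiked)
  expect_true(any(iss$type == "spike"))
  expect_true(any(iss$where == 100))

  short <- make_static_recording(n = 70, fs = 140)  # 0.5 s
  expect_true(any(validate_recording(short)$type == "too_short"))

  gappy <- rec
  gappy$index[50:53, ] <- NaN
  expect_true(any(validate_recording(gappy)$type == "gap"))
})

test_that("parameters table writes tidily, sorts rows and round-trips", {
  rows <- do.call(rbind, lapply(1:3, function(k) {
    tr <- gen_reach_trial(trial_spec(seed = k), "P01",
                          "TC", c("C", "A", "B")[k], 4L - k)
    extract_trial(tr$recording)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameters_table(rows, path)
  back <- read_parameters_table(path)

  expect_equal(nrow(back), 3)
  expect_true(all(PARAM_NAMES <- c("MT", "MWV", "MWDec", "MTD", "MGA",
                                   "MGCV", "TMWV", "TMWDec", "TMTD",
                                   "TMGA", "TMGCV") %in% names(back)))
  expect_equal(back$condition, c("A", "B", "C"))  # sorted
  ord <- order(rows$condition)
  for (p in PARAM_NAMES)
    expect_equal(back[[p]], rows[[p]][ord], tolerance = 1e-9)

  expect_error(write_parameters_table(rows[0, ], path),
               class = "reachkin_empty_output_error")
})

test_that("cohort and CPT logs are parsed and counted under both codings", {
  meta <- data.frame(participant_id = c("a", "b"), group = c("TC", "Control"),
                     years_practice = c(10, 0))
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(meta, p, row.names = FALSE)
  expect_equal(read_cohort_csv(p)$years_practice, c(10, 0))

  log <- data.frame(participant_id = "a", trial_index = 1:6,
                    is_target = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    responded = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  cw <- cpt_counts(log, coding = "withhold")
  expect_equal(cw$hits, 1)          # withheld on 1 of 2 targets
  expect_equal(cw$false_alarms, 1)  # withheld on 1 of 4 non-targets
  cr <- cpt_counts(log, coding = "respond")
  expect_equal(cr$hits, 1)
  expect_equal(cr$false_alarms, 3)
})
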