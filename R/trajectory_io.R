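# Trial / cohort I/O and recording validation.
#
# The on-disk trial format is a plain CSV with commented metadata header
# lines ("# key=value") followed by a wide table, one row per sample:
# time, wrist_x, wrist_y, wrist_z, thumb_x, ..., index_z. Units are fixed at
# the I/O boundary: positions in mm, time in seconds, fs in Hz. Axes: x is
# the reach direction, y is vertical, z completes a right-handed frame
# (positive z = rightward trajectory deviation).

MARKERS <- c("wrist", "thumb", "index")
TRIAL_COLUMNS <- c("time", as.vector(t(outer(MARKERS, c("x", "y", "z"),
                                             paste, sep = "_"))))

#' Construct a trial recording
#'
#' A `trial_recording` bundles the three marker tracks of one reach-to-grasp
#' trial (wrist, thumb, index; mm, uniformly sampled) with its metadata.
#'
#' @param participant_id Participant identifier (character scalar).
#' @param group Group label, `"TC"` or `"Control"`.
#' @param condition Imagery condition, one of `"A"`–`"E"` (still water,
#'   flowing water, wave, whirlpool, opening water flower).
#' @param trial_index Trial number within the condition (integer >= 1).
#' @param fs Sampling rate in Hz (study value: 140).
#' @param t Sample times in seconds, strictly increasing with step `1/fs`.
#' @param wrist,thumb,index n x 3 numeric matrices of marker positions in mm,
#'   columns x, y, z.
#'
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(participant_id, group, condition, trial_index,
                            fs, t, wrist, thumb, index) {
  if (!group %in% GROUPS)
    rk_abort(sprintf("group must be one of %s", paste(GROUPS, collapse = ", ")),
             "format")
  if (!condition %in% CONDITIONS)
    rk_abort("condition must be one of A, B, C, D, E", "format")
  if (!is.numeric(fs) || fs <= 0) rk_abort("fs must be positive", "format")
  n <- length(t)
  if (n < 2) rk_abort("recording needs at least 2 samples", "format")
  for (m in list(wrist, thumb, index)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3)
      rk_abort("marker tracks must be n x 3 matrices matching t", "format")
  }
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6)
    rk_abort("sample times must increase uniformly at 1/fs (tol 1e-6 s)",
             "sampling")
  structure(
    list(participant_id = as.character(participant_id), group = group,
         condition = condition, trial_index = as.integer(trial_index),
         fs = fs, t = as.numeric(t),
         wrist = unname(wrist), thumb = unname(thumb), index = unname(index)),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s | group %s | condition %s | trial %d | %d samples @ %g Hz (%.2f s)\n",
    x$participant_id, x$group, x$condition, x$trial_index,
    length(x$t), x$fs, length(x$t) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [trial_recording()].
#' @return Duration `n / fs` in seconds.
#' @export
recording_duration <- function(rec) length(rec$t) / rec$fs

#' Extract one marker track as a data frame
#'
#' @param rec A [trial_recording()].
#' @param label One of `"wrist"`, `"thumb"`, `"index"`.
#' @return A data frame with columns `label`, `t`, `x`, `y`, `z`.
#' @export
marker_track <- function(rec, label = c("wrist", "thumb", "index")) {
  label <- match.arg(label)
  m <- rec[[label]]
  data.frame(label = label, t = rec$t, x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Read a trial CSV
#'
#' Parses the package's trial dialect: commented `# key=value` metadata lines
#' (participant, group, condition, trial, fs) followed by a wide sample table.
#'
#' @param path Path to a trial CSV file.
#' @param strict If `TRUE` (default), runs of missing samples raise a gap
#'   error naming the sample range; if `FALSE` they are kept for
#'   [validate_recording()] to report.
#' @return A validated [trial_recording()].
#' @export
read_trial_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) rk_abort(paste("no such file:", path), "format")
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  need <- c("participant", "group", "condition", "trial", "fs")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    rk_abort(paste("missing metadata keys:", paste(miss, collapse = ", ")),
             "format")
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols))
    rk_abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
             "format")
  if (strict) {
    bad <- which(!stats::complete.cases(df[TRIAL_COLUMNS]))
    if (length(bad))
      rk_abort(sprintf("missing samples (gap) in rows %d-%d",
                       min(bad), max(bad)), "gap")
  }
  grab <- function(m) as.matrix(df[paste(m, c("x", "y", "z"), sep = "_")])
  trial_recording(meta$participant, meta$group, meta$condition,
                  as.integer(meta$trial), as.numeric(meta$fs),
                  df$time, grab("wrist"), grab("thumb"), grab("index"))
}

#' Write a trial CSV
#'
#' Inverse of [read_trial_csv()]. Numeric fields are written at 1e-6
#' precision (micrometre / microsecond), at which read/write round-trips are
#' exact.
#'
#' @param rec A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(rec, path) {
  hdr <- c(sprintf("# participant=%s", rec$participant_id),
           sprintf("# group=%s", rec$group),
           sprintf("# condition=%s", rec$condition),
           sprintf("# trial=%d", rec$trial_index),
           sprintf("# fs=%g", rec$fs))
  m <- cbind(rec$t, rec$wrist, rec$thumb, rec$index)
  body <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = ","))
  writeLines(c(hdr, paste(TRIAL_COLUMNS, collapse = ","), body), path)
  invisible(path)
}

#' Validate a recording
#'
#' Mirrors the per-trial quality check applied before analysis: reports
#' missing-sample gaps, single-step position jumps larger than 100 mm
#' (marker-identification spikes), and recordings shorter than 0.7 s (too
#' short to satisfy the 500 ms onset-sustain rule plus margin).
#'
#' @param rec A [trial_recording()].
#' @param spike_mm Single-step jump size flagged as a spike (mm).
#' @param min_duration_s Minimum acceptable recording duration (s).
#' @return A data frame of issues with columns `type`, `where`, `detail`;
#'   zero rows when the recording is clean.
#' @export
validate_recording <- function(rec, spike_mm = 100, min_duration_s = 0.7) {
  issues <- list()
  add <- function(type, where, detail)
    issues[[length(issues) + 1]] <<- data.frame(
      type = type, where = where, detail = detail)
  for (m in MARKERS) {
    pos <- rec[[m]]
    bad <- which(!is.finite(rowSums(pos)))
    if (length(bad)) {
      runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
      for (r in runs)
        add("gap", min(r), sprintf("%s samples %d-%d missing", m, min(r), max(r)))
    }
    ok <- which(is.finite(rowSums(pos)))
    if (length(ok) > 1) {
      step <- sqrt(rowSums(diff(pos[ok, , drop = FALSE])^2))
      spikes <- which(step > spike_mm)
      for (s in spikes)
        add("spike", ok[s + 1],
            sprintf("%s jumps %.1f mm at sample %d", m, step[s], ok[s + 1]))
    }
  }
  if (recording_duration(rec) < min_duration_s)
    add("too_short", 1L,
        sprintf("duration %.3f s < %.2f s", recording_duration(rec),
                min_duration_s))
  if (!length(issues))
    return(data.frame(type = character(), where = integer(),
                      detail = character()))
  do.call(rbind, issues)
}

#' Write a tidy parameters table
#'
#' One row per trial, metadata columns (participant, group, condition, trial)
#' followed by the eleven kinematic parameters; rows ordered by
#' (participant, condition, trial). Values are written at full double
#' precision so a write/read round trip preserves them to better than 1e-9.
#'
#' @param rows Data frame of trial parameters, e.g. rbind-ed outputs of
#'   [extract_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters_table <- function(rows, path) {
  if (is.null(rows) || !nrow(rows))
    rk_abort("no parameter rows to write", "empty_output")
  meta_cols <- c("participant", "group", "condition", "trial")
  need <- c(meta_cols, PARAM_NAMES)
  miss <- setdiff(need, names(rows))
  if (length(miss))
    rk_abort(paste("parameter rows missing columns:",
                   paste(miss, collapse = ", ")), "format")
  extra <- setdiff(names(rows), need)
  rows <- rows[order(rows$participant, rows$condition, rows$trial),
               c(need, extra)]
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy parameters table written by [write_parameters_table()]
#' @param path CSV path.
#' @return Data frame of per-trial parameters.
#' @export
read_parameters_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("participant", "group", "condition", "trial", PARAM_NAMES),
                  names(df))
  if (length(miss))
    rk_abort(paste("parameters table missing columns:",
                   paste(miss, collapse = ", ")), "format")
  df$participant <- as.character(df$participant)
  df
}

#' Read cohort metadata (participant_id, group, years_practice)
#' @param path CSV path.
#' @return Data frame with one row per participant.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("participant_id", "group", "years_practice"), names(df))
  if (length(miss))
    rk_abort(paste("cohort table missing columns:",
                   paste(miss, collapse = ", ")), "format")
  if (anyDuplicated(df$participant_id))
    rk_abort("participant_id values must be unique", "format")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Read a trial-level CPT response log
#'
#' Expected columns: `participant_id`, `trial_index`, `is_target` (logical or
#' 0/1; TRUE for the critical stimulus), `responded` (logical or 0/1).
#'
#' @param path CSV path.
#' @return Data frame of CPT events.
#' @export
read_cpt_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("participant_id", "trial_index", "is_target", "responded"),
                  names(df))
  if (length(miss))
    rk_abort(paste("CPT log missing columns:", paste(miss, collapse = ", ")),
             "format")
  df$participant_id <- as.character(df$participant_id)
  df$is_target <- as.logical(df$is_target)
  df$responded <- as.logical(df$responded)
  df
}
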