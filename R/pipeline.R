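# File-based pipeline: simulate -> extract -> analyze -> report. Stage
# boundaries are plain files (trial CSVs, tidy tables), so every stage can be
# re-run independently and outputs are byte-reproducible for a fixed config
# and seed.

#' Default pipeline configuration
#'
#' Defaults reproduce the study constants: 140 Hz sampling, 6 Hz low-pass
#' cutoff, 5 mm/s onset/offset thresholds with a 500 ms onset sustain, 15 +
#' 14 participants with ten trials in each of the five imagery conditions,
#' and a 600-trial CPT with a 5% critical-stimulus rate.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    filter = list(cutoff_hz = 6, order = 2),
    onset = list(threshold_mm_s = 5, sustain_ms = 500),
    offset = list(threshold_mm_s = 5),
    strict_boundaries = FALSE,
    cohort = list(n_tc = 15, n_control = 14, trials_per_cell = 10,
                  intercept_share = 0.5, trial_sd_frac = 0.5,
                  noise_sd = c(0.3, 0.2, 0.3), fs = 140),
    cpt = list(n_trials = 600, target_rate = 0.05, criterion = 0.5,
               n_per_group = 13,
               mean_dprime = c(TC = 0.98, Control = 0.01),
               sd_dprime = c(TC = 0.82, Control = 1.17),
               coding = "withhold"),
    stats = list(bonferroni_family = 5, ddf = "satterthwaite"))
}

#' Read a pipeline configuration from YAML
#'
#' Values given in the file override the defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return Configuration list.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        rk_abort(paste0("unknown config key: ", prefix, k), "config")
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  cfg <- merge_cfg(base, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Simulate a cohort dataset to disk
#'
#' Writes trial CSVs (`trials/`), cohort metadata (`meta.csv`), per-trial
#' clean-trajectory ground truth (`ground_truth.csv`), and simulated CPT
#' counts (`cpt.csv`) under `out_dir`.
#'
#' @param config Configuration list ([default_config()] shape).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  cc <- config$cohort
  if (cc$n_tc + cc$n_control < 1)
    rk_abort("cohort must contain at least one participant", "config")
  dir.create(file.path(out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  cs <- cohort_spec(n_tc = cc$n_tc, n_control = cc$n_control,
                    trials_per_cell = cc$trials_per_cell,
                    intercept_share = cc$intercept_share,
                    trial_sd_frac = cc$trial_sd_frac,
                    noise_sd = cc$noise_sd, fs = cc$fs, seed = config$seed)
  cohort <- gen_cohort(cs)
  for (rec in cohort$recordings) {
    fn <- sprintf("%s_%s_%02d.csv", rec$participant_id, rec$condition,
                  rec$trial_index)
    write_trial_csv(rec, file.path(out_dir, "trials", fn))
  }
  utils::write.csv(cohort$meta, file.path(out_dir, "meta.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  cp <- config$cpt
  cpt <- gen_cpt_cohort(n_per_group = cp$n_per_group,
                        mean_dprime = unlist(cp$mean_dprime),
                        sd_dprime = unlist(cp$sd_dprime),
                        criterion = cp$criterion,
                        n_signal = round(cp$n_trials * cp$target_rate),
                        n_noise = round(cp$n_trials * (1 - cp$target_rate)),
                        seed = derive_seed(config$seed, 99991))
  utils::write.csv(cpt, file.path(out_dir, "cpt.csv"), row.names = FALSE)
  message(sprintf("simulated %d trials for %d participants",
                  length(cohort$recordings), nrow(cohort$meta)))
  invisible(out_dir)
}

#' Extract kinematic parameters for every trial in a dataset
#'
#' Reads each trial CSV, validates it, and extracts the eleven parameters.
#' Trials failing validation or segmentation are excluded and logged to
#' `exclusions.log` next to the output table (one line per exclusion with the
#' trial identity and reason).
#'
#' @param config Configuration list.
#' @param dataset_dir Directory produced by [pipeline_simulate()] (or
#'   arranged the same way).
#' @param out_file Output CSV for the tidy parameter table.
#' @return Invisibly, the parameter table.
#' @export
pipeline_extract <- function(config, dataset_dir, out_file) {
  files <- sort(list.files(file.path(dataset_dir, "trials"),
                           pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) rk_abort("dataset contains no trial files", "format")
  rows <- list()
  exclusions <- character()
  for (f in files) {
    res <- tryCatch({
      rec <- read_trial_csv(f, strict = FALSE)
      issues <- validate_recording(rec)
      if (nrow(issues))
        stop(sprintf("validation: %s", paste(issues$detail, collapse = "; ")))
      extract_trial(rec, cutoff = config$filter$cutoff_hz,
                    onset_threshold = config$onset$threshold_mm_s,
                    offset_threshold = config$offset$threshold_mm_s,
                    sustain = config$onset$sustain_ms / 1000)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      exclusions <- c(exclusions, sprintf("%s: %s", basename(f), res))
    } else if (config$strict_boundaries && nzchar(res$flags)) {
      exclusions <- c(exclusions,
                      sprintf("%s: boundary extremum (%s)", basename(f),
                              res$flags))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (!length(rows)) rk_abort("all trials were excluded", "empty_output")
  tab <- do.call(rbind, rows)
  write_parameters_table(tab, out_file)
  writeLines(exclusions, file.path(dirname(out_file), "exclusions.log"))
  message(sprintf("extracted %d trials, excluded %d", nrow(tab),
                  length(exclusions)))
  invisible(tab)
}

#' Run the full statistical analysis on a parameter table
#'
#' Per-parameter mixed models with post hocs and the Session-E contrast, the
#' Range table, Range-on-years regressions for every parameter, the d' group
#' comparison (when CPT counts are available), and the cell/marginal summary.
#' Results are written as CSVs under `out_dir`.
#'
#' @param config Configuration list.
#' @param params_file Tidy parameter CSV ([pipeline_extract()] output).
#' @param dataset_dir Dataset directory (for `meta.csv` and `cpt.csv`).
#' @param out_dir Output directory.
#' @return Invisibly, a list of the result tables.
#' @export
pipeline_analyze <- function(config, params_file, dataset_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- read_parameters_table(params_file)
  meta <- read_cohort_csv(file.path(dataset_dir, "meta.csv"))

  two_groups <- length(unique(tidy$group)) >= 2
  model_rows <- list()
  posthoc_rows <- list()
  contrast_rows <- list()
  if (two_groups) {
    for (p in PARAM_NAMES) {
      fit <- fit_condition_group_model(tidy, p)
      model_rows[[p]] <- cbind(parameter = p, fit$anova)
      posthoc_rows[[p]] <- cbind(parameter = p, fit$posthoc)
      contrast_rows[[p]] <- cbind(parameter = p, fit$contrast_E)
    }
  } else {
    rk_warn("single-group input: group tests skipped", "design")
  }

  ranges <- range_table(tidy)
  reg_rows <- lapply(PARAM_NAMES, function(p)
    tryCatch(regress_range_on_years(ranges, meta, p),
             reachkin_error = function(e) NULL))
  regressions <- do.call(rbind, reg_rows[!vapply(reg_rows, is.null, TRUE)])

  summ <- group_condition_summary(tidy)

  out <- list(models = do.call(rbind, model_rows),
              posthoc = do.call(rbind, posthoc_rows),
              contrasts = do.call(rbind, contrast_rows),
              ranges = ranges, regressions = regressions,
              cells = summ$cells, marginals = summ$marginals)

  cpt_file <- file.path(dataset_dir, "cpt.csv")
  if (file.exists(cpt_file)) {
    cpt <- utils::read.csv(cpt_file)
    cpt$dprime <- loglinear_dprime(cpt$hits, cpt$false_alarms, cpt$n_signal,
                                   cpt$n_noise)
    utils::write.csv(cpt[c("participant_id", "group", "dprime")],
                     file.path(out_dir, "dprime.csv"), row.names = FALSE)
    if (two_groups) out$dprime_test <- compare_dprime(cpt)
  }

  for (nm in names(out)) {
    if (!is.null(out[[nm]]) && is.data.frame(out[[nm]]))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(out)
}

#' Write a human-readable analysis report
#'
#' @param analysis_dir Directory written by [pipeline_analyze()].
#' @param out_file Output markdown file.
#' @return `out_file`, invisibly.
#' @export
pipeline_report <- function(analysis_dir, out_file) {
  rd <- function(f) {
    p <- file.path(analysis_dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  models <- rd("models.csv")
  marg <- rd("marginals.csv")
  ranges <- rd("ranges.csv")
  reg <- rd("regressions.csv")
  dpt <- rd("dprime_test.csv")
  lines <- c("# Reach-to-grasp kinematic analysis", "")
  if (is.null(models) && is.null(marg)) {
    lines <- c(lines, "no results")
  } else {
    if (!is.null(marg)) {
      lines <- c(lines, "## Group marginal means", "")
      for (p in unique(marg$parameter)) {
        sub <- marg[marg$parameter == p, ]
        lines <- c(lines, sprintf(
          "- %s: %s", p,
          paste(sprintf("%s %.3g", sub$group, sub$mean), collapse = ", ")))
      }
      lines <- c(lines, "")
    }
    if (!is.null(models)) {
      lines <- c(lines, "## Mixed-model fixed effects (p < .05)", "")
      sig <- models[models$p < 0.05, ]
      if (nrow(sig))
        lines <- c(lines, sprintf(
          "- %s, %s: F(%d, %.1f) = %.2f, p = %.4g", sig$parameter,
          sig$effect, sig$df1, sig$df2, sig$F, sig$p))
      else lines <- c(lines, "- none")
      lines <- c(lines, "")
    }
    if (!is.null(reg) && nrow(reg)) {
      lines <- c(lines, "## Range ~ years of practice", "",
                 sprintf("- %s: beta = %.2f, F(1, %d) = %.2f, p = %.4g, R2 = %.2f",
                         reg$parameter, reg$beta, reg$df2, reg$F, reg$p,
                         reg$r_squared), "")
    }
    if (!is.null(dpt)) {
      lines <- c(lines, "## CPT sensitivity", "",
                 sprintf("- d': %.2f (practitioners) vs %.2f (controls), t(%d) = %.2f, p = %.4g, Cohen's d = %.2f",
                         dpt$mean_tc, dpt$mean_control, dpt$df, dpt$t, dpt$p,
                         dpt$cohens_d), "")
    }
    if (!is.null(ranges)) {
      lines <- c(lines, sprintf("Ranges computed for %d participants x %d parameters.",
                                length(unique(ranges$participant_id)),
                                length(unique(ranges$parameter))))
    }
  }
  writeLines(lines, out_file)
  invisible(out_file)
}

#' Run the whole pipeline end to end
#'
#' @param config Configuration list.
#' @param out_dir Root output directory (`dataset/`, `parameters.csv`,
#'   `analysis/`, `report.md` inside).
#' @return Invisibly, the analysis result list.
#' @export
pipeline_run_all <- function(config, out_dir) {
  ds <- file.path(out_dir, "dataset")
  pipeline_simulate(config, ds)
  pf <- file.path(out_dir, "parameters.csv")
  pipeline_extract(config, ds, pf)
  res <- pipeline_analyze(config, pf, ds, file.path(out_dir, "analysis"))
  pipeline_report(file.path(out_dir, "analysis"),
                  file.path(out_dir, "report.md"))
  invisible(res)
}
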