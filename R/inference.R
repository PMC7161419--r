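# Inferential layer: per-parameter linear mixed models (Session within, Group
# between, participant random intercept), Bonferroni post hocs, the
# opening-water-flower (Session E) planned contrast, Range-on-years
# regressions, the d' group comparison, and descriptive cell summaries.
#
# Trial-level rows are averaged to participant x condition means before
# modelling: the resulting denominator degrees of freedom are on the
# participant scale (e.g. 27 for the Group effect with 29 participants), the
# scale on which repeated-measures prehension studies report their tests.

#' Participant-by-condition means of one parameter
#'
#' @param tidy_params Tidy trial table ([extract_trial()] rows).
#' @param dv Parameter column name (e.g. `"MGCV"`).
#' @return Data frame `participant`, `group`, `condition`, `value`.
#' @export
participant_condition_means <- function(tidy_params, dv) {
  if (!dv %in% names(tidy_params))
    rk_abort(paste("no such parameter column:", dv), "format")
  agg <- stats::aggregate(
    tidy_params[[dv]],
    by = list(participant = tidy_params$participant,
              group = tidy_params$group,
              condition = tidy_params$condition),
    FUN = mean)
  names(agg)[4] <- "value"
  agg
}

#' Fit the Session-within / Group-between mixed model for one parameter
#'
#' REML linear mixed model `value ~ group * condition + (1 | participant)` on
#' participant x condition means, with sum-to-zero contrasts, Type-III F
#' tests with Satterthwaite denominator degrees of freedom, within-session
#' group post hocs (Bonferroni over the five sessions), and the planned
#' contrast of Session E against the mean of Sessions A–D.
#'
#' @param tidy_params Tidy trial table.
#' @param dv Parameter column name.
#' @param posthoc Compute the within-session post hocs and the Session-E
#'   contrast (default `TRUE`); switch off when only the omnibus F tests are
#'   needed (e.g. in calibration simulations).
#' @return Object of class `rk_mixed_model`: list with `parameter`, `model`,
#'   `anova` (effect, F, df1, df2, p), `posthoc` (session, estimate
#'   (TC - Control), t, df, p_bonferroni), `contrast_E` (estimate, t, df, p),
#'   `singular`.
#' @export
fit_condition_group_model <- function(tidy_params, dv, posthoc = TRUE) {
  d <- participant_condition_means(tidy_params, dv)
  if (length(unique(d$group)) < 2)
    rk_abort("need both groups to fit the group model", "design")
  if (!all(CONDITIONS %in% d$condition))
    rk_abort("all five sessions (A-E) must be present", "design")
  tab <- table(d$group) / length(CONDITIONS)
  if (any(tab < 2))
    rk_abort("need at least 2 participants per group", "design")
  d$group <- factor(d$group, levels = GROUPS)
  d$condition <- factor(d$condition, levels = CONDITIONS)
  d$participant <- factor(d$participant)

  m <- lmerTest::lmer(
    value ~ group * condition + (1 | participant), data = d, REML = TRUE,
    contrasts = list(group = "contr.sum", condition = "contr.sum"))
  singular <- lme4::isSingular(m)
  if (singular)
    rk_warn(paste0(dv, ": participant variance estimated at zero; ",
                   "model reduces to its fixed-effect structure"),
            "singular_fit")

  an <- stats::anova(m, type = 3, ddf = "Satterthwaite")
  anova_df <- data.frame(
    effect = rownames(an), F = an[["F value"]], df1 = an$NumDF,
    df2 = an$DenDF, p = an[["Pr(>F)"]], row.names = NULL)

  ph_tab <- NULL
  ce <- NULL
  if (posthoc) {
    emm <- suppressMessages(
      emmeans::emmeans(m, ~ group | condition, lmer.df = "satterthwaite"))
    ph <- emmeans::contrast(emm, "pairwise")
    ph <- summary(stats::update(ph, by = NULL), adjust = "bonferroni")
    ph_tab <- data.frame(
      session = CONDITIONS,
      estimate = ph$estimate, t = ph$t.ratio, df = ph$df,
      p_bonferroni = ph$p.value)
    ce <- planned_contrast_E(m)
  }

  structure(list(parameter = dv, model = m, anova = anova_df,
                 posthoc = ph_tab, contrast_E = ce, singular = singular),
            class = "rk_mixed_model")
}

#' @export
print.rk_mixed_model <- function(x, ...) {
  cat(sprintf("<rk_mixed_model> %s\n", x$parameter))
  print(x$anova, digits = 4)
  if (!is.null(x$contrast_E))
    cat(sprintf("Session E vs mean(A-D): est %.4g, t(%.1f) = %.2f, p = %.4g\n",
                x$contrast_E$estimate, x$contrast_E$df, x$contrast_E$t,
                x$contrast_E$p))
  invisible(x)
}

#' Planned contrast: Session E against the mean of Sessions A–D
#'
#' Contrast weights (-1/4, -1/4, -1/4, -1/4, 1) on the session estimated
#' marginal means (Satterthwaite df).
#'
#' @param model A fitted `lmerMod` / `lmerModLmerTest` from
#'   [fit_condition_group_model()], or the `rk_mixed_model` itself.
#' @return Data frame row: `estimate`, `se`, `t`, `df`, `p`.
#' @export
planned_contrast_E <- function(model) {
  if (inherits(model, "rk_mixed_model")) model <- model$model
  emm <- emmeans::emmeans(model, ~ condition, lmer.df = "satterthwaite")
  lv <- summary(emm)$condition
  if (!setequal(lv, CONDITIONS))
    rk_abort("model must contain all five sessions A-E", "design")
  w <- ifelse(CONDITIONS == "E", 1, -0.25)[match(lv, CONDITIONS)]
  con <- summary(emmeans::contrast(emm, method = list(E_vs_rest = w)))
  data.frame(estimate = con$estimate, se = con$SE, t = con$t.ratio,
             df = con$df, p = con$p.value)
}

#' Regress a Range parameter on years of practice
#'
#' Ordinary least squares on practitioners only (years of practice is
#' undefined for controls). The standardized coefficient of a
#' single-predictor model satisfies `beta^2 = R^2`.
#'
#' @param ranges Range table from [range_table()].
#' @param meta Cohort metadata ([read_cohort_csv()] format).
#' @param parameter Which Range parameter to regress (e.g. `"TMGCV"`).
#' @return Data frame row: `parameter`, `n`, `beta` (standardized), `F`,
#'   `df1`, `df2`, `p`, `r_squared`.
#' @export
regress_range_on_years <- function(ranges, meta, parameter) {
  sel <- ranges$parameter == parameter
  d <- merge(ranges[sel, c("participant_id", "range_value")], meta,
             by = "participant_id")
  d <- d[d$group == "TC", ]
  if (nrow(d) < 3) rk_abort("need at least 3 practitioners", "design")
  if (stats::sd(d$years_practice) < 1e-12)
    rk_abort("years of practice has zero variance", "degenerate_design")
  fit <- stats::lm(range_value ~ years_practice, data = d)
  sm <- summary(fit)
  beta <- stats::coef(fit)[2] * stats::sd(d$years_practice) /
    stats::sd(d$range_value)
  data.frame(parameter = parameter, n = nrow(d), beta = unname(beta),
             F = unname(sm$fstatistic[1]), df1 = 1, df2 = nrow(d) - 2,
             p = unname(stats::pf(sm$fstatistic[1], 1, nrow(d) - 2,
                                  lower.tail = FALSE)),
             r_squared = sm$r.squared)
}

#' Independent-samples comparison of d' between groups
#'
#' Two-sided pooled-variance t-test and Cohen's d (pooled SD).
#'
#' @param dprimes Data frame with columns `group` and `dprime` (one row per
#'   participant).
#' @return Data frame row: `mean_tc`, `mean_control`, `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
compare_dprime <- function(dprimes) {
  x <- dprimes$dprime[dprimes$group == "TC"]
  y <- dprimes$dprime[dprimes$group == "Control"]
  if (length(x) < 2 || length(y) < 2)
    rk_abort("need at least 2 participants per group", "design")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 < 1e-14) rk_abort("zero pooled variance", "degenerate")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  data.frame(mean_tc = mean(x), mean_control = mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohens_d = (mean(x) - mean(y)) / sqrt(sp2))
}

#' Group x condition cell summary and group marginals
#'
#' Cell means and SDs are computed over participants' trial means; group
#' marginal means are equal-weight means of the five condition cells. When
#' participant-level data are available the marginal SD is the SD of the
#' participants' own across-condition means.
#'
#' @param tidy_params Tidy trial table.
#' @param parameters Parameter columns to summarise (default: all eleven).
#' @return List with `cells` (group, condition, parameter, mean, sd, n,
#'   flag) and `marginals` (group, parameter, mean, sd).
#' @export
group_condition_summary <- function(tidy_params, parameters = PARAM_NAMES) {
  cells <- list()
  marg <- list()
  for (p in parameters) {
    pm <- participant_condition_means(tidy_params, p)
    for (g in unique(pm$group)) {
      for (cc in CONDITIONS) {
        v <- pm$value[pm$group == g & pm$condition == cc]
        if (!length(v))
          rk_abort(sprintf("empty cell: %s / %s / %s", g, cc, p),
                   "missing_cell")
        cells[[length(cells) + 1]] <- data.frame(
          group = g, condition = cc, parameter = p, mean = mean(v),
          sd = if (length(v) > 1) stats::sd(v) else NA_real_,
          n = length(v),
          flag = if (length(v) > 1) "" else "single_participant")
      }
      sub <- pm[pm$group == g, ]
      pmarg <- tapply(sub$value, sub$participant, mean)
      cellm <- tapply(sub$value, sub$condition, mean)
      marg[[length(marg) + 1]] <- data.frame(
        group = g, parameter = p, mean = mean(cellm),
        sd = if (length(pmarg) > 1) stats::sd(pmarg) else NA_real_)
    }
  }
  list(cells = do.call(rbind, cells), marginals = do.call(rbind, marg))
}

#' Group marginals from a cell-statistics table
#'
#' Applies the equal-weight marginal rule directly to a table of cell means
#' (e.g. the calibration table from [cohort_reference_stats()]), without
#' participant-level data.
#'
#' @param cells Data frame with columns `group`, `condition`, `parameter`,
#'   `mean`.
#' @return Data frame `group`, `parameter`, `mean` (mean of the five
#'   condition cells).
#' @export
cell_marginals <- function(cells) {
  agg <- stats::aggregate(cells$mean,
                          by = list(group = cells$group,
                                    parameter = cells$parameter),
                          FUN = mean)
  names(agg)[3] <- "mean"
  agg
}
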