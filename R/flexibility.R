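# Motor-flexibility Range index and signal-detection sensitivity (d') for the
# continuous performance test (CPT).

#' Range (motor-flexibility) index
#'
#' Difference between the maximum and the minimum of a participant's
#' per-condition values of one kinematic parameter. Larger ranges across
#' imagery conditions are read as greater motor flexibility.
#'
#' @param values_by_condition Named numeric vector (or list) of per-condition
#'   means; at least two conditions.
#' @return Non-negative scalar, `max - min`.
#' @export
compute_range <- function(values_by_condition) {
  v <- unlist(values_by_condition)
  if (length(v) < 2)
    rk_abort("Range needs values from at least two conditions",
             "insufficient_conditions")
  if (!all(is.finite(v))) rk_abort("non-finite condition values", "format")
  max(v) - min(v)
}

#' Per-participant Range table
#'
#' Aggregates a tidy trial-parameter table to participant x condition means,
#' then computes the Range of every kinematic parameter for every
#' participant.
#'
#' @param tidy_params Data frame as produced by [extract_trial()] /
#'   [read_parameters_table()].
#' @param parameters Parameter columns to use (default: all eleven).
#' @return Data frame with columns `participant_id`, `group`, `parameter`,
#'   `range_value`.
#' @export
range_table <- function(tidy_params, parameters = PARAM_NAMES) {
  miss <- setdiff(parameters, names(tidy_params))
  if (length(miss))
    rk_abort(paste("missing parameter columns:", paste(miss, collapse = ", ")),
             "format")
  out <- list()
  for (pid in unique(tidy_params$participant)) {
    sub <- tidy_params[tidy_params$participant == pid, ]
    for (p in parameters) {
      cond_means <- tapply(sub[[p]], sub$condition, mean)
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid, group = sub$group[1], parameter = p,
        range_value = compute_range(cond_means))
    }
  }
  do.call(rbind, out)
}

#' Loglinear-corrected d-prime
#'
#' Equal-variance signal-detection sensitivity with the loglinear correction:
#' 0.5 is added to the hit and false-alarm counts and 1 to the signal and
#' noise trial counts before taking normal quantiles, so d' stays finite at
#' perfect or zero rates.
#'
#' @param hits,false_alarms Counts of hits and false alarms.
#' @param n_signal,n_noise Numbers of signal (critical-stimulus) and noise
#'   trials.
#' @return d' (dimensionless): `qnorm((hits+0.5)/(n_signal+1)) -
#'   qnorm((false_alarms+0.5)/(n_noise+1))`.
#' @export
loglinear_dprime <- function(hits, false_alarms, n_signal, n_noise) {
  if (any(hits < 0 | hits > n_signal) ||
      any(false_alarms < 0 | false_alarms > n_noise))
    rk_abort("counts must satisfy 0 <= hits <= n_signal, 0 <= FA <= n_noise",
             "format")
  stats::qnorm((hits + 0.5) / (n_signal + 1)) -
    stats::qnorm((false_alarms + 0.5) / (n_noise + 1))
}

#' Hit / false-alarm counts from a CPT response log
#'
#' In a respond-to-all-letters-but-X task the mapping of button presses to
#' hits is ambiguous; both codings are supported. With `coding = "withhold"`
#' (default) a hit is a correctly withheld response on a critical (X) trial
#' and a false alarm an incorrectly withheld response on a noise trial; with
#' `coding = "respond"` a hit is a press on a critical trial and a false
#' alarm a press on a noise trial.
#'
#' @param cpt_log Data frame from [read_cpt_csv()] (one participant or many).
#' @param coding `"withhold"` or `"respond"`.
#' @return Data frame with one row per participant: `participant_id`,
#'   `n_signal`, `n_noise`, `hits`, `false_alarms`, `dprime`.
#' @export
cpt_counts <- function(cpt_log, coding = c("withhold", "respond")) {
  coding <- match.arg(coding)
  hit_event <- if (coding == "withhold") !cpt_log$responded else
    cpt_log$responded
  out <- lapply(split(seq_len(nrow(cpt_log)), cpt_log$participant_id),
                function(ix) {
    tgt <- cpt_log$is_target[ix]
    data.frame(participant_id = cpt_log$participant_id[ix[1]],
               n_signal = sum(tgt), n_noise = sum(!tgt),
               hits = sum(hit_event[ix] & tgt),
               false_alarms = sum(hit_event[ix] & !tgt))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$dprime <- loglinear_dprime(out$hits, out$false_alarms,
                                 out$n_signal, out$n_noise)
  out
}
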