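# Trial-aligned net responses, the joint response criterion, and the
# multiunit leaky-integrator AUC measure.

#' Net response of one unit to one stimulus under one light condition
#'
#' The net response is the spike count during the stimulus window minus the
#' count during the matched prestimulus window, averaged across trials.
#' Baselines are computed per light condition, because activating the
#' inhibitory network also depresses resting activity. The across-trial
#' sample SD of the prestimulus counts is retained for the response
#' criterion; with a single trial the SD is undefined and flagged.
#'
#' @param spikes A [spike_train].
#' @param trials A [taste_trials] table already restricted to the trials to
#'   aggregate (typically one unit x stimulus x light condition); or a full
#'   table together with `stimulus` / `light_condition` selectors.
#' @param stimulus,light_condition Optional selectors applied to `trials`.
#' @return A one-row data frame of class `net_response`: `unit_id`,
#'   `stimulus`, `light_condition`, `net_spikes_per_window`, `n_trials`,
#'   `baseline_mean`, `baseline_sd` (NA when undefined), `window_s`.
#' @examples
#' st <- spike_train("u1", c(sort(runif(28, 10, 20)), sort(runif(10, 0, 10))))
#' tr <- taste_trials(data.frame(
#'   trial_id = "T1", stimulus = "SUC", stim_onset_s = 10, stim_dur_s = 10,
#'   prestim_onset_s = 0, prestim_dur_s = 10, light_condition = "control"
#' ))
#' net_response(st, tr)
#' @export
net_response <- function(spikes, trials, stimulus = NULL,
                         light_condition = NULL) {
  stopifnot(inherits(spikes, "spike_train"), inherits(trials, "taste_trials"))
  if ("unit_id" %in% names(trials)) {
    trials <- trials[is.na(trials$unit_id) | trials$unit_id == spikes$unit_id, ,
                     drop = FALSE]
  }
  if (!is.null(stimulus)) trials <- trials[trials$stimulus == stimulus, , drop = FALSE]
  if (!is.null(light_condition)) {
    trials <- trials[trials$light_condition == light_condition, , drop = FALSE]
  }
  if (nrow(trials) < 1) stop("no trials selected", call. = FALSE)
  if (length(unique(trials$stimulus)) > 1 ||
      length(unique(trials$light_condition)) > 1) {
    stop("trials span more than one stimulus or light condition", call. = FALSE)
  }
  over <- which(trials$stim_onset_s + trials$stim_dur_s > spikes$t_stop + 1e-9 |
                  trials$prestim_onset_s < -1e-9)
  if (length(over)) {
    stop(sprintf("analysis window of trial %s lies outside the recording span",
                 trials$trial_id[over[1]]), call. = FALSE)
  }
  stim_n <- mapply(count_spikes, onset = trials$stim_onset_s,
                   duration = trials$stim_dur_s,
                   MoreArgs = list(x = spikes))
  pre_n <- mapply(count_spikes, onset = trials$prestim_onset_s,
                  duration = trials$prestim_dur_s,
                  MoreArgs = list(x = spikes))
  out <- data.frame(
    unit_id = spikes$unit_id,
    stimulus = trials$stimulus[1],
    light_condition = trials$light_condition[1],
    net_spikes_per_window = mean(stim_n - pre_n),
    n_trials = nrow(trials),
    baseline_mean = mean(pre_n),
    baseline_sd = if (nrow(trials) >= 2) stats::sd(pre_n) else NA_real_,
    window_s = trials$stim_dur_s[1]
  )
  class(out) <- c("net_response", class(out))
  out
}

#' Full response profile of one unit
#'
#' Computes a [net_response] for every stimulus x light condition present in
#' the trial table, plus the best stimulus per condition (maximum net
#' response, ties broken by panel order) and the unit's spontaneous rate
#' (control prestimulus rate).
#'
#' @param spikes A [spike_train].
#' @param trials A [taste_trials] table for the session.
#' @param panel A [stimulus_panel]; fixes stimulus order and tie-breaks.
#' @return Data frame of class `response_profile` (one row per stimulus x
#'   condition) with attributes `unit_id`, `best_stimulus` (named by
#'   condition) and `spontaneous_rate_hz`.
#' @export
response_profile <- function(spikes, trials, panel) {
  stopifnot(inherits(panel, "stimulus_panel"))
  if ("unit_id" %in% names(trials)) {
    trials <- trials[is.na(trials$unit_id) | trials$unit_id == spikes$unit_id, ,
                     drop = FALSE]
  }
  combos <- unique(trials[, c("stimulus", "light_condition")])
  combos <- combos[order(match(combos$stimulus, panel$stimuli),
                         match(combos$light_condition, .light_conditions)), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    net_response(spikes, trials, stimulus = combos$stimulus[i],
                 light_condition = combos$light_condition[i])
  })
  prof <- do.call(rbind, rows)
  best <- vapply(unique(prof$light_condition), function(cond) {
    sub <- prof[prof$light_condition == cond, ]
    sub$stimulus[which.max(sub$net_spikes_per_window)] # first max = panel order
  }, character(1))
  ctrl <- prof[prof$light_condition == "control", ]
  spont <- if (nrow(ctrl)) {
    stats::weighted.mean(ctrl$baseline_mean / ctrl$window_s, ctrl$n_trials)
  } else NA_real_
  structure(prof,
            class = c("response_profile", class(prof)),
            unit_id = spikes$unit_id, best_stimulus = best,
            spontaneous_rate_hz = spont)
}

#' Joint response criterion
#'
#' A stimulus counts as a response when the net evoked rate is at least
#' `rate_threshold` Hz (10 spikes over a 10-s window at the default 1 Hz)
#' AND the net count is at least `sd_mult` (default 2.5) times the
#' across-trial SD of the baseline-window counts. For mouth-light responses
#' the baseline window is an equal-length unstimulated period, so the same
#' arithmetic applies. A single-trial input has no defined baseline SD and
#' raises an error unless a `fallback_sd` is supplied; the two historical
#' exceptions to the criterion are supported only through the explicit
#' `override` flag, which is recorded in the output rather than silently
#' applied.
#'
#' @param net A `net_response` row (or several) from [net_response()].
#' @param rate_threshold Net evoked rate clause, Hz (default 1).
#' @param sd_mult Baseline-SD multiplier (default 2.5).
#' @param fallback_sd Baseline SD (spikes/window) to use when only one trial
#'   is available; default `NULL` raises an error in that case.
#' @param override Logical: force `significant = TRUE` regardless of the
#'   criterion (recorded in the `override` column).
#' @return `net` with logical columns `significant` and `override` appended.
#' @export
apply_criterion <- function(net, rate_threshold = 1, sd_mult = 2.5,
                            fallback_sd = NULL, override = FALSE) {
  stopifnot(inherits(net, "net_response") || all(
    c("net_spikes_per_window", "baseline_sd", "window_s") %in% names(net)))
  sd_use <- net$baseline_sd
  if (anyNA(sd_use)) {
    if (is.null(fallback_sd)) {
      stop("baseline SD undefined (single trial) and no fallback_sd given",
           call. = FALSE)
    }
    sd_use[is.na(sd_use)] <- fallback_sd
  }
  rate_ok <- net$net_spikes_per_window >= rate_threshold * net$window_s
  sd_ok <- net$net_spikes_per_window >= sd_mult * sd_use
  net$significant <- (rate_ok & sd_ok) | override
  net$override <- rep(override, nrow(net))
  net
}

#' Flag significant responses throughout a response profile
#'
#' Convenience wrapper applying [apply_criterion()] row-wise to a
#' [response_profile], preserving its attributes.
#'
#' @inheritParams apply_criterion
#' @param profile A `response_profile`.
#' @return The profile with `significant` and `override` columns.
#' @export
flag_responses <- function(profile, rate_threshold = 1, sd_mult = 2.5,
                           fallback_sd = NULL) {
  at <- attributes(profile)
  out <- apply_criterion(profile, rate_threshold, sd_mult, fallback_sd)
  for (a in c("unit_id", "best_stimulus", "spontaneous_rate_hz")) {
    attr(out, a) <- at[[a]]
  }
  class(out) <- unique(c("response_profile", class(out)))
  out
}

#' Multiunit integrated-AUC response
#'
#' Quantifies multiunit activity by leaky integration of binned spike
#' counts (exponential decay with time constant `tau`), then takes the area
#' under the integrated trace during the stimulation window minus the area
#' during the immediately preceding baseline window. The filter is run from
#' the start of the trace so its transient has died away before the
#' windows. Use [normalize_to_max_control()] to express a set of such
#' responses relative to the maximum control response of a subject.
#'
#' @param spikes A [spike_train], or a numeric vector of spike times.
#' @param stim_window,baseline_window Length-2 numeric `c(start, end)` in
#'   seconds; the two windows are typically equal length.
#' @param tau Integrator time constant, s (default 0.1). Must be > 0.
#' @param bin Bin width for the count trace, s (default 0.01).
#' @return Scalar: baseline-adjusted AUC (spike x seconds, unnormalized).
#' @export
multiunit_auc <- function(spikes, stim_window, baseline_window,
                          tau = 0.1, bin = 0.01) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$timestamps
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  stopifnot(length(stim_window) == 2, length(baseline_window) == 2)
  if (diff(stim_window) <= 0 || diff(baseline_window) <= 0) {
    stop("empty analysis window", call. = FALSE)
  }
  t_max <- max(stim_window[2], baseline_window[2])
  edges <- seq(0, t_max + bin, by = bin)
  counts <- graphics::hist(spikes[spikes >= 0 & spikes < t_max],
                           breaks = edges, plot = FALSE)$counts
  decay <- exp(-bin / tau)
  y <- stats::filter(counts, decay, method = "recursive")
  centers <- edges[-length(edges)] + bin / 2
  auc_in <- function(w) sum(y[centers >= w[1] & centers < w[2]]) * bin
  auc_in(stim_window) - auc_in(baseline_window)
}

#' @rdname multiunit_auc
#' @param responses Numeric vector of (unnormalized) responses.
#' @param is_control Logical vector marking the control-condition entries
#'   whose maximum defines the normalizer.
#' @return `normalize_to_max_control()`: `responses` divided by the maximum
#'   control response, so the maximum control response maps to 1.
#' @export
normalize_to_max_control <- function(responses, is_control) {
  stopifnot(length(responses) == length(is_control), any(is_control))
  m <- max(responses[is_control])
  if (m <= 0) stop("maximum control response must be > 0", call. = FALSE)
  responses / m
}
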