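# Ground-truth generator for rNST-like recording sessions and brief-access
# lick sessions. Spiking is piecewise-homogeneous Poisson with additive
# pulse-locked spikes for ChR2 units; inhibition under brain light acts
# multiplicatively (gain g in [0,1]) on the evoked rate and, separately, on
# the spontaneous rate, with an optional subtractive offset (Hz). Defaults
# are calibrated to the printed population summaries of the recordings the
# analysis targets: ~96% per-pulse following at 1 Hz, ~5.9 +/- 0.7 ms
# first-spike latency/jitter for ChR2 units, putative GABA taste cells
# responding at roughly 0.37 x the gain of non-GABA taste cells.

.seed_mod <- 2147483647

# Deterministic per-unit substream seed: adding a unit never perturbs the
# spike trains of units already in the session.
.derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% .seed_mod
  as.integer((abs(master) %% .seed_mod * 48271 + h) %% .seed_mod)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a simulated neuron
#'
#' Parameterizes one unit of the generator: its cell class (non-GABA taste
#' cell `G_minus_taste`; ChR2-expressing GABA taste cell `G_plus_taste`;
#' ChR2-expressing cell unresponsive to oral stimuli `G_plus_unr`),
#' spontaneous rate, per-stimulus evoked rates (Hz above baseline), ChR2
#' tagging parameters, and how brain light suppresses it: evoked rate
#' becomes `max(0, gain * evoked - offset)` and spontaneous rate
#' `gain_spont * spontaneous` (by default `gain_spont = gain`, since GABA
#' network activation also depresses resting activity).
#'
#' @param unit_id Unit label.
#' @param cell_class One of `"G_minus_taste"`, `"G_plus_taste"`,
#'   `"G_plus_unr"`.
#' @param spontaneous_rate Baseline firing rate, Hz. Defaults by class
#'   (non-GABA taste cells fire fastest at rest, unresponsive GABA cells are
#'   commonly silent): 8, 3 and 0 Hz.
#' @param evoked_rate Named numeric, evoked rate above baseline (Hz) per
#'   stimulus. Must be all zero for `G_plus_unr`.
#' @param chr2 Does the unit express ChR2 (respond to brain light pulses)?
#'   Defaults to `TRUE` for the two GABA classes.
#' @param tag_latency_mean,tag_jitter_sd Pulse-locked spike latency mean and
#'   SD, ms. Defaults 5.9 and 0.72.
#' @param follow_prob Per-pulse probability of an evoked spike, default 0.96.
#' @param gain Multiplicative suppression in `[0, 1]` under brain light.
#' @param offset Subtractive suppression, Hz, under brain light (default 0).
#' @param gain_spont Multiplicative suppression of the spontaneous rate
#'   under brain light; default `NULL` means "same as `gain`".
#' @return Object of class `neuron_spec`.
#' @export
neuron_spec <- function(unit_id,
                        cell_class = c("G_minus_taste", "G_plus_taste",
                                       "G_plus_unr"),
                        spontaneous_rate = NULL,
                        evoked_rate = numeric(),
                        chr2 = NULL,
                        tag_latency_mean = 5.9,
                        tag_jitter_sd = 0.72,
                        follow_prob = 0.96,
                        gain = 1,
                        offset = 0,
                        gain_spont = NULL) {
  cell_class <- match.arg(cell_class)
  if (is.null(spontaneous_rate)) {
    spontaneous_rate <- switch(cell_class,
      G_minus_taste = 8, G_plus_taste = 3, G_plus_unr = 0)
  }
  if (is.null(chr2)) chr2 <- cell_class != "G_minus_taste"
  stopifnot(spontaneous_rate >= 0, all(evoked_rate >= 0),
            gain >= 0, gain <= 1, follow_prob >= 0, follow_prob <= 1,
            offset >= 0)
  if (cell_class == "G_plus_unr" && length(evoked_rate) && any(evoked_rate > 0)) {
    stop("G_plus_unr units must have all evoked rates 0", call. = FALSE)
  }
  if (length(evoked_rate) && is.null(names(evoked_rate))) {
    stop("evoked_rate must be named by stimulus", call. = FALSE)
  }
  structure(
    list(unit_id = as.character(unit_id), cell_class = cell_class,
         spontaneous_rate = spontaneous_rate, evoked_rate = evoked_rate,
         chr2 = chr2, tag_latency_mean = tag_latency_mean,
         tag_jitter_sd = tag_jitter_sd, follow_prob = follow_prob,
         gain = gain, offset = offset,
         gain_spont = gain_spont %||% gain),
    class = "neuron_spec"
  )
}

#' Replication plan for a simulated session
#'
#' @param panel A [stimulus_panel].
#' @param n_control,n_light Trials per stimulus under `control` and
#'   `light_br`. Two replications per condition mirror a typical session.
#' @return Data frame with columns `stimulus`, `light_condition`, `n`.
#' @export
trial_plan <- function(panel, n_control = 2, n_light = 2) {
  stopifnot(inherits(panel, "stimulus_panel"))
  plan <- expand.grid(stimulus = panel$stimuli,
                      light_condition = .light_conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan$n <- ifelse(plan$light_condition == "control", n_control, n_light)
  plan[plan$n > 0, , drop = FALSE]
}

# Sample a homogeneous Poisson segment on [a, b) at `rate` Hz.
.poisson_segment <- function(rate, a, b) {
  if (rate <= 0 || b <= a) return(double())
  n <- stats::rpois(1L, rate * (b - a))
  if (n == 0L) return(double())
  sort(stats::runif(n, a, b))
}

# Enforce an absolute refractory period by dropping the later spike of any
# pair closer than `refractory` seconds.
.apply_refractory <- function(ts, refractory) {
  while (length(ts) > 1L) {
    bad <- which(diff(ts) < refractory)
    if (!length(bad)) break
    ts <- ts[-(bad + 1L)]
  }
  ts
}

#' Simulate a taste-testing session
#'
#' Generates a full recording session for a population of units: taste
#' trials (10-s artificial-saliva prestimulus window, 10-s stimulus window)
#' under control and brain-light conditions, brain-light pulse trains during
#' light trials (10 Hz by default) and dedicated optotagging pulse blocks,
#' and spike trains per unit. Spiking is piecewise-homogeneous Poisson at
#' `spontaneous + evoked` with the spec'd suppression under `light_br`;
#' ChR2 units additionally fire one pulse-locked spike per brain-light
#' pulse with probability `follow_prob`, at a Normal(latency, jitter) delay.
#' A 1-ms absolute refractory period is enforced by default. Identical
#' arguments and seed reproduce the output exactly, and per-unit seed
#' substreams mean that adding a unit does not perturb the others.
#'
#' @param specs List of [neuron_spec] objects.
#' @param panel A [stimulus_panel].
#' @param plan A [trial_plan] data frame.
#' @param seed Integer master seed.
#' @param stim_dur,prestim_dur,gap_s Window and inter-trial gap durations, s.
#' @param light_covers_prestim Should brain light span the prestimulus
#'   window as well as the stimulus window on `light_br` trials (default
#'   `TRUE`; light-trial baselines are computed separately downstream)?
#' @param brain_light_hz Brain-light pulse rate during light trials.
#' @param pulse_width_s Light pulse width, s (default 0.005).
#' @param tag_frequencies Pulse rates of the optotagging blocks appended
#'   after the taste trials (default 1, 4, 10, 20, 50 Hz).
#' @param tag_n_pulses Pulses per optotagging block (default 20).
#' @param refractory_s Absolute refractory period, s; `0` disables.
#' @return List with elements `spikes` (named list of [spike_train]),
#'   `trials` ([taste_trials]), `pulses` ([pulse_trains]) and `ground_truth`
#'   (all parameters plus the seed; sufficient to regenerate the dataset).
#' @export
simulate_session <- function(specs, panel, plan, seed,
                             stim_dur = 10, prestim_dur = 10, gap_s = 5,
                             light_covers_prestim = TRUE,
                             brain_light_hz = 10, pulse_width_s = 0.005,
                             tag_frequencies = c(1, 4, 10, 20, 50),
                             tag_n_pulses = 20,
                             refractory_s = 0.001) {
  if (inherits(specs, "neuron_spec")) specs <- list(specs)
  stopifnot(length(specs) > 0, inherits(panel, "stimulus_panel"))
  unknown <- setdiff(plan$stimulus, panel$stimuli)
  if (length(unknown)) {
    stop("plan stimuli not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  # --- trial table -------------------------------------------------------
  rows <- plan[rep(seq_len(nrow(plan)), plan$n), c("stimulus", "light_condition")]
  t0 <- 2
  trial_len <- prestim_dur + stim_dur + gap_s
  n_tr <- nrow(rows)
  trials <- data.frame(
    trial_id = sprintf("T%03d", seq_len(n_tr)),
    stimulus = rows$stimulus,
    stim_onset_s = t0 + (seq_len(n_tr) - 1) * trial_len + prestim_dur,
    stim_dur_s = stim_dur,
    prestim_onset_s = t0 + (seq_len(n_tr) - 1) * trial_len,
    prestim_dur_s = prestim_dur,
    light_condition = rows$light_condition,
    row.names = NULL
  )
  trials <- taste_trials(trials)

  # --- brain-light pulse trains -----------------------------------------
  pulse_rows <- list()
  for (i in seq_len(n_tr)) {
    if (trials$light_condition[i] != "light_br") next
    a <- if (light_covers_prestim) trials$prestim_onset_s[i] else trials$stim_onset_s[i]
    b <- trials$stim_onset_s[i] + trials$stim_dur_s[i]
    on <- seq(a, b - 1 / brain_light_hz, by = 1 / brain_light_hz)
    pulse_rows[[length(pulse_rows) + 1L]] <- data.frame(
      train_id = paste0("BL_", trials$trial_id[i]), target = "brain",
      light_condition = "light_br", nominal_hz = brain_light_hz,
      pulse_width_s = pulse_width_s, onset_s = on
    )
  }
  tag_start <- t0 + n_tr * trial_len + gap_s
  for (f in tag_frequencies) {
    on <- tag_start + (seq_len(tag_n_pulses) - 1) / f
    pulse_rows[[length(pulse_rows) + 1L]] <- data.frame(
      train_id = sprintf("TAG_%gHz", f), target = "brain",
      light_condition = "light_br", nominal_hz = f,
      pulse_width_s = pulse_width_s, onset_s = on
    )
    tag_start <- tag_start + tag_n_pulses / f + gap_s
  }
  pulses <- pulse_trains(if (length(pulse_rows)) {
    do.call(rbind, pulse_rows)
  } else {
    data.frame(train_id = character(), target = character(),
               light_condition = character(), nominal_hz = double(),
               pulse_width_s = double(), onset_s = double())
  })
  t_end <- tag_start + gap_s
  brain_onsets <- pulses$onset_s[pulses$target == "brain"]

  # --- spikes per unit ---------------------------------------------------
  clamped <- FALSE
  spikes <- list()
  for (sp in specs) {
    stopifnot(inherits(sp, "neuron_spec"))
    ts <- .with_seed(.derive_seed(seed, sp$unit_id), {
      out <- double()
      cursor <- 0
      for (i in seq_len(n_tr)) {
        light <- trials$light_condition[i] == "light_br"
        pre_a <- trials$prestim_onset_s[i]
        stim_a <- trials$stim_onset_s[i]
        stim_b <- stim_a + trials$stim_dur_s[i]
        spont_pre <- sp$spontaneous_rate *
          if (light && light_covers_prestim) sp$gain_spont else 1
        spont_stim <- sp$spontaneous_rate * if (light) sp$gain_spont else 1
        ev <- unname(sp$evoked_rate[trials$stimulus[i]])
        if (is.na(ev) || !length(ev)) ev <- 0
        ev_eff <- if (light) sp$gain * ev - sp$offset else ev
        if (ev_eff < 0) {
          clamped <- TRUE
          ev_eff <- 0
        }
        out <- c(out,
                 .poisson_segment(sp$spontaneous_rate, cursor, pre_a),
                 .poisson_segment(spont_pre, pre_a, stim_a),
                 .poisson_segment(spont_stim + ev_eff, stim_a, stim_b))
        cursor <- stim_b
      }
      out <- c(out, .poisson_segment(sp$spontaneous_rate, cursor, t_end))
      if (sp$chr2 && length(brain_onsets)) {
        hit <- stats::runif(length(brain_onsets)) < sp$follow_prob
        lat <- stats::rnorm(sum(hit), sp$tag_latency_mean, sp$tag_jitter_sd)
        out <- c(out, brain_onsets[hit] + lat / 1000)
      }
      out <- sort(out[out >= 0 & out <= t_end])
      if (refractory_s > 0) out <- .apply_refractory(out, refractory_s)
      out
    })
    spikes[[sp$unit_id]] <- spike_train(sp$unit_id, ts, t_stop = t_end)
  }
  if (clamped) {
    warning("some light_br evoked rates clamped at 0 Hz", call. = FALSE)
  }

  gt <- structure(
    list(seed = seed, panel = unclass(panel),
         plan = plan, specs = lapply(specs, unclass),
         stim_dur = stim_dur, prestim_dur = prestim_dur, gap_s = gap_s,
         light_covers_prestim = light_covers_prestim,
         brain_light_hz = brain_light_hz,
         tag_frequencies = tag_frequencies, tag_n_pulses = tag_n_pulses,
         refractory_s = refractory_s),
    class = "ground_truth"
  )
  list(spikes = structure(spikes, class = "spike_train_list"),
       trials = trials, pulses = pulses, ground_truth = gt)
}

#' Default mouth-light frequency-response function
#'
#' Entrained evoked rate as a function of nominal pulse frequency: rises
#' roughly linearly at low frequencies, peaks near `f_peak`, then declines —
#' the saturating shape seen when light frequency stands in for tastant
#' concentration.
#'
#' @param peak_rate Evoked rate (Hz) at the peak frequency.
#' @param f_peak Frequency (Hz) of the peak response, default 15 Hz.
#' @return A function of frequency returning evoked rate in Hz.
#' @export
lightm_rate_fun <- function(peak_rate = 12, f_peak = 15) {
  force(peak_rate); force(f_peak)
  function(f) peak_rate * (f / f_peak) * exp(1 - f / f_peak)
}

#' Simulate a mouth-light frequency series
#'
#' Generates 2-s mouth-light pulse blocks at each nominal frequency, under
#' control and (optionally) concurrent brain-light conditions, for one unit.
#' Each block is preceded by an equal-length unstimulated window serving as
#' its baseline. Entrained spikes follow each mouth pulse with probability
#' `rate_fun(f)/f` (capped at 1), so the expected evoked rate traces
#' `rate_fun`; under `light_br` the evoked rate is suppressed exactly as in
#' [simulate_session].
#'
#' @param spec A [neuron_spec] (its `gain`/`offset` set the suppression).
#' @param frequencies Nominal pulse frequencies, Hz. Must be nonempty.
#' @param seed Integer seed.
#' @param duration Block duration, s (default 2).
#' @param n_reps Replicate blocks per frequency x condition.
#' @param conditions Light conditions to simulate.
#' @param rate_fun Frequency-response function; default [lightm_rate_fun()].
#' @param response_latency_ms,response_jitter_ms Latency distribution of the
#'   entrained spikes after each mouth pulse.
#' @param gap_s Gap between blocks, s.
#' @return List with `spikes` (one [spike_train]), `trials` (block windows
#'   as a [taste_trials] table, stimulus labels `LM<f>`), `pulses`
#'   ([pulse_trains], target `"mouth"`).
#' @export
simulate_lightm_series <- function(spec, frequencies = c(2, 5, 10, 20, 50),
                                   seed = 1, duration = 2, n_reps = 2,
                                   conditions = c("control", "light_br"),
                                   rate_fun = lightm_rate_fun(),
                                   response_latency_ms = 15,
                                   response_jitter_ms = 3,
                                   gap_s = 3) {
  stopifnot(inherits(spec, "neuron_spec"))
  if (!length(frequencies)) stop("empty frequency list", call. = FALSE)
  stopifnot(all(frequencies > 0), all(conditions %in% .light_conditions))

  grid <- expand.grid(rep = seq_len(n_reps), frequency = frequencies,
                      light_condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  t0 <- 2
  block_len <- 2 * duration + gap_s
  n_bl <- nrow(grid)
  trials <- taste_trials(data.frame(
    trial_id = sprintf("LM%03d", seq_len(n_bl)),
    stimulus = sprintf("LM%g", grid$frequency),
    stim_onset_s = t0 + (seq_len(n_bl) - 1) * block_len + duration,
    stim_dur_s = duration,
    prestim_onset_s = t0 + (seq_len(n_bl) - 1) * block_len,
    prestim_dur_s = duration,
    light_condition = grid$light_condition
  ))
  pulse_rows <- lapply(seq_len(n_bl), function(i) {
    f <- grid$frequency[i]
    a <- trials$stim_onset_s[i]
    data.frame(train_id = paste0("LM_", trials$trial_id[i]), target = "mouth",
               light_condition = grid$light_condition[i], nominal_hz = f,
               pulse_width_s = 0.005,
               onset_s = seq(a, a + duration - 1 / f, by = 1 / f))
  })
  pulses <- pulse_trains(do.call(rbind, pulse_rows))
  t_end <- t0 + n_bl * block_len + gap_s

  ts <- .with_seed(.derive_seed(seed, paste0("lm_", spec$unit_id)), {
    out <- .poisson_segment(spec$spontaneous_rate, 0, t_end)
    # suppress spontaneous activity during light_br blocks
    if (spec$gain_spont < 1) {
      for (i in which(trials$light_condition == "light_br")) {
        a <- trials$prestim_onset_s[i]
        b <- trials$stim_onset_s[i] + trials$stim_dur_s[i]
        inside <- out >= a & out < b
        keep <- stats::runif(length(out)) < spec$gain_spont
        out <- out[!inside | keep]
      }
    }
    for (i in seq_len(n_bl)) {
      f <- grid$frequency[i]
      r <- rate_fun(f)
      if (grid$light_condition[i] == "light_br") {
        r <- max(0, spec$gain * r - spec$offset)
      }
      p <- min(1, r / f)
      on <- pulses$onset_s[pulses$train_id == paste0("LM_", trials$trial_id[i])]
      hit <- stats::runif(length(on)) < p
      lat <- stats::rnorm(sum(hit), response_latency_ms, response_jitter_ms)
      out <- c(out, on[hit] + lat / 1000)
    }
    out <- sort(out[out >= 0 & out <= t_end])
    .apply_refractory(out, 0.001)
  })
  list(spikes = spike_train(spec$unit_id, ts, t_stop = t_end),
       trials = trials, pulses = pulses)
}

#' Specify a simulated mouse for the brief-access lick study
#'
#' @param mouse_id Mouse label.
#' @param modal_ili_ms Modal interlick interval, ms (default 115.5, a
#'   typical water-deprived mouse under saline).
#' @param ili_sd_ms SD of within-burst interlick intervals, ms.
#' @param logistic_params Named list with elements `saline` and `CNO`, each
#'   `c(min, max, logec50, hill)` of the concentration-response logistic on
#'   `log10(concentration)`. Defaults approximate a sucrose study: half-max
#'   near 228 mM under saline, right-shifted to ~252 mM under CNO.
#' @param slr_noise_sd Trial-to-trial SD added to the target standardized
#'   lick ratio (default 0.05).
#' @param pause_prob Probability that any interlick interval is interrupted
#'   by a pause.
#' @param pause_mean_ms Mean added pause duration, ms.
#' @return Object of class `lick_spec`.
#' @export
lick_spec <- function(mouse_id, modal_ili_ms = 115.5, ili_sd_ms = 8,
                      logistic_params = list(
                        saline = c(min = 0.1, max = 0.95,
                                   logec50 = log10(228), hill = 2),
                        CNO = c(min = 0.1, max = 0.95,
                                logec50 = log10(252), hill = 2)
                      ),
                      slr_noise_sd = 0.05,
                      pause_prob = 0.02, pause_mean_ms = 700) {
  stopifnot(modal_ili_ms > 0, ili_sd_ms >= 0,
            all(c("saline", "CNO") %in% names(logistic_params)))
  for (p in logistic_params) {
    stopifnot(all(c("min", "max", "logec50", "hill") %in% names(p)))
    if (p[["min"]] > p[["max"]]) stop("logistic min > max", call. = FALSE)
  }
  structure(
    list(mouse_id = as.character(mouse_id), modal_ili_ms = modal_ili_ms,
         ili_sd_ms = ili_sd_ms, logistic_params = logistic_params,
         slr_noise_sd = slr_noise_sd, pause_prob = pause_prob,
         pause_mean_ms = pause_mean_ms),
    class = "lick_spec"
  )
}

#' Simulate a brief-access lick study
#'
#' For each mouse and drug condition, generates brief-access trials at each
#' concentration: the trial's target standardized lick ratio comes from the
#' mouse's logistic concentration-response for that drug plus Gaussian noise
#' (clamped to `[0, 1.05]`), the lick count is the target ratio times the
#' maximum licks possible at the modal interlick interval, and timestamps
#' are laid down at Normal(modal ILI, ILI SD) intervals truncated above 50
#' ms with occasional pauses. With `include_water = TRUE`, water trials at a
#' near-maximal lick ratio are added (needed for water-relative quinine
#' ratios).
#'
#' @param lick_specs List of [lick_spec] objects.
#' @param concentrations Numeric concentrations tested.
#' @param n_trials Trials per concentration per drug condition.
#' @param seed Integer master seed.
#' @param stimulus Stimulus label (default `"SUC"`).
#' @param conc_units Concentration units label (default `"mM"`).
#' @param access_dur Access duration from first lick, s (default 5).
#' @param include_water Add water trials (`n_trials` per drug)?
#' @return A [lick_table] covering all mice and drug conditions.
#' @export
simulate_lick_study <- function(lick_specs, concentrations, n_trials, seed,
                                stimulus = "SUC", conc_units = "mM",
                                access_dur = 5, include_water = FALSE) {
  if (inherits(lick_specs, "lick_spec")) lick_specs <- list(lick_specs)
  stopifnot(length(concentrations) >= 1, n_trials >= 1)
  rows <- list()
  for (ls in lick_specs) {
    stopifnot(inherits(ls, "lick_spec"))
    for (drug in c("saline", "CNO")) {
      rows[[length(rows) + 1L]] <-
        .with_seed(.derive_seed(seed, paste0(ls$mouse_id, "_", drug)), {
          p <- ls$logistic_params[[drug]]
          conc_seq <- c(rep(concentrations, each = n_trials),
                        if (include_water) rep(NA_real_, n_trials))
          out <- vector("list", length(conc_seq))
          max_licks <- access_dur / (ls$modal_ili_ms / 1000)
          for (j in seq_along(conc_seq)) {
            conc <- conc_seq[j]
            target <- if (is.na(conc)) 1 else {
              logistic_response(log10(conc), p[["min"]], p[["max"]],
                                p[["logec50"]], p[["hill"]])
            }
            slr <- min(1.05, max(0, target + stats::rnorm(1, 0, ls$slr_noise_sd)))
            n_licks <- round(slr * max_licks)
            tt <- if (n_licks >= 1) {
              ili <- stats::rnorm(max(0, n_licks - 1), ls$modal_ili_ms,
                                  ls$ili_sd_ms)
              ili <- pmax(ili, 50.001)
              pause <- stats::runif(length(ili)) < ls$pause_prob
              ili[pause] <- ili[pause] +
                stats::rexp(sum(pause), 1 / ls$pause_mean_ms)
              cumsum(c(0, ili)) / 1000
            } else NA_real_
            out[[j]] <- data.frame(
              mouse_id = ls$mouse_id,
              session_id = paste0("sess_", drug),
              drug = drug,
              trial_id = sprintf("%s_%s_%03d", ls$mouse_id, drug, j),
              stimulus = if (is.na(conc)) "WATER" else stimulus,
              concentration = if (is.na(conc)) 0 else conc,
              conc_units = conc_units,
              access_dur_s = access_dur,
              lick_t_s = tt
            )
          }
          do.call(rbind, out)
        })
    }
  }
  lick_table(do.call(rbind, rows))
}
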