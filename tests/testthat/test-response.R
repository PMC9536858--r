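test_that("net response is the mean stimulus-minus-prestimulus count", {
  trials <- make_trials(2)
  st <- spikes_in_windows("u1",
    onsets = c(trials$prestim_onset_s, trials$stim_onset_s),
    durations = rep(10, 4), counts = c(10, 14, 28, 32))
  net <- net_response(st, trials)
  expect_equal(net$net_spikes_per_window, 18) # ((28-10)+(32-14))/2
  expect_equal(net$n_trials, 2)
  expect_equal(net$baseline_mean, 12)
})

test_that("baseline SD is the across-trial sample SD of prestimulus counts", {
  trials <- make_trials(4)
  st <- spikes_in_windows("u1",
    onsets = c(trials$prestim_onset_s, trials$stim_onset_s),
    durations = rep(10, 8), counts = c(10, 14, 12, 12, 20, 20, 20, 20))
  net <- net_response(st, trials)
  expect_equal(net$baseline_sd, 1.632993, tolerance = 1e-6)
  # equal counts in both windows on every trial => net 0
  st0 <- spikes_in_windows("u1",
    onsets = c(trials$prestim_onset_s, trials$stim_onset_s),
    durations = rep(10, 8), counts = rep(c(7, 9, 11, 13), 2))
  expect_equal(net_response(st0, trials)$net_spikes_per_window, 0)
})

test_that("windows outside the recording span are rejected by trial id", {
  trials <- make_trials(2)
  st <- spike_train("u1", c(1, 5, 12), t_stop = 30) # trial T02 ends at 45
  expect_error(net_response(st, trials), "T02")
})

test_that("the joint criterion needs both the rate and the SD clause", {
  base <- data.frame(unit_id = "u", stimulus = "SUC",
                     light_condition = "control", n_trials = 2,
                     baseline_mean = 12, window_s = 10)
  mk <- function(net, sd) {
    out <- cbind(base, net_spikes_per_window = net, baseline_sd = sd)
    class(out) <- c("net_response", class(out))
    out
  }
  expect_true(apply_criterion(mk(18, 1.633))$significant)   # 18 >= 10, >= 4.08
  expect_false(apply_criterion(mk(9, 0.1))$significant)     # fails rate clause
  expect_true(apply_criterion(mk(10, 0))$significant)       # boundary: 10/10 s
  expect_false(apply_criterion(mk(12, 6))$significant)      # 12 < 2.5 * 6
  # single trial: no SD -> explicit error, never a silent pass
  expect_error(apply_criterion(mk(50, NA_real_)), "fallback_sd")
  expect_true(apply_criterion(mk(50, NA_real_), fallback_sd = 2)$significant)
  # manual override is recorded, not silent
  ov <- apply_criterion(mk(9, 0.1), override = TRUE)
  expect_true(ov$significant)
  expect_true(ov$override)
})

test_that("net responses are invariant to spikes added to both windows", {
  trials <- make_trials(3)
  k <- 5
  st1 <- spikes_in_windows("u1",
    onsets = c(trials$prestim_onset_s, trials$stim_onset_s),
    durations = rep(10, 6), counts = c(8, 10, 12, 30, 28, 35))
  st2 <- spikes_in_windows("u1",
    onsets = c(trials$prestim_onset_s, trials$stim_onset_s),
    durations = rep(10, 6), counts = c(8, 10, 12, 30, 28, 35) + k)
  expect_equal(net_response(st1, trials)$net_spikes_per_window,
               net_response(st2, trials)$net_spikes_per_window)
})

test_that("response profiles pick the best stimulus with panel-order ties", {
  panel <- standard_panel("A")
  specs <- neuron_spec("u", "G_minus_taste", spontaneous_rate = 1,
                       evoked_rate = c(SUC = 6, NaCl = 2))
  sim <- simulate_session(specs, panel, trial_plan(panel, 3, 0), seed = 2,
                          tag_frequencies = numeric(0))
  prof <- response_profile(sim$spikes$u, sim$trials, panel)
  expect_equal(unname(attr(prof, "best_stimulus")["control"]), "SUC")
  expect_equal(nrow(prof), 5)
  expect_equal(attr(prof, "spontaneous_rate_hz"), 1, tolerance = 0.5)
  flagged <- flag_responses(prof)
  expect_true(flagged$significant[flagged$stimulus == "SUC"])
})

test_that("multiunit AUC is baseline-adjusted, linear, and normalizable", {
  # stationary activity, equal windows -> response ~ 0
  ts <- seq(0.005, 40, by = 0.05) # steady 20 Hz
  a <- multiunit_auc(ts, stim_window = c(20, 30), baseline_window = c(10, 20))
  expect_lt(abs(a), 1e-6)

  # doubling all counts doubles the unnormalized response
  evoked <- sort(c(ts, seq(25.003, 30, by = 0.025)))
  doubled <- sort(rep(evoked, each = 2))
  r1 <- multiunit_auc(evoked, c(20, 30), c(10, 20))
  r2 <- multiunit_auc(doubled, c(20, 30), c(10, 20))
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
  expect_gt(r1, 0)

  # the maximum control response maps to 1 after normalization
  resp <- c(3.2, 5.1, 4.4, 2.0)
  is_ctrl <- c(TRUE, TRUE, FALSE, FALSE)
  norm <- normalize_to_max_control(resp, is_ctrl)
  expect_equal(max(norm[is_ctrl]), 1)
  expect_equal(norm, resp / 5.1)

  expect_error(multiunit_auc(ts, c(20, 30), c(10, 20), tau = 0), "tau")
  expect_error(multiunit_auc(ts, c(30, 30), c(10, 20)), "empty")
})

test_that("criterion false-positive rate under a 20-Hz Poisson null stays low", {
  # quick null check at the highest baseline; the full operating
  # characteristics run in the acceptance suite
  panel <- standard_panel("A")
  spec <- neuron_spec("u", "G_minus_taste", spontaneous_rate = 20,
                      evoked_rate = c(SUC = 0))
  plan <- data.frame(stimulus = "SUC", light_condition = "control", n = 3)
  hits <- vapply(1:200, function(s) {
    sim <- simulate_session(spec, panel, plan, seed = s,
                            tag_frequencies = numeric(0))
    net <- net_response(sim$spikes$u, sim$trials)
    apply_criterion(net)$significant
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
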