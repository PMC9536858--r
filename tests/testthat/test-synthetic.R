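panel5 <- standard_panel("A")

test_that("identical specs and seed reproduce the session bit-for-bit", {
  specs <- population_specs(3, 1, 1, panel5, seed = 7, gain = 0.5)
  a <- simulate_session(specs, panel5, trial_plan(panel5), seed = 42)
  b <- simulate_session(specs, panel5, trial_plan(panel5), seed = 42)
  expect_identical(lapply(a$spikes, `[[`, "timestamps"),
                   lapply(b$spikes, `[[`, "timestamps"))
  expect_identical(as.data.frame(a$trials), as.data.frame(b$trials))
  c <- simulate_session(specs, panel5, trial_plan(panel5), seed = 43)
  expect_false(identical(lapply(a$spikes, `[[`, "timestamps"),
                         lapply(c$spikes, `[[`, "timestamps")))
})

test_that("adding a unit does not perturb existing units' spike trains", {
  s1 <- list(neuron_spec("a", "G_minus_taste", 2, c(SUC = 3)))
  s2 <- c(s1, list(neuron_spec("b", "G_minus_taste", 2, c(SUC = 3))))
  plan <- data.frame(stimulus = "SUC", light_condition = "control", n = 2)
  a <- simulate_session(s1, panel5, plan, seed = 5)
  b <- simulate_session(s2, panel5, plan, seed = 5)
  expect_identical(a$spikes$a$timestamps, b$spikes$a$timestamps)
})

test_that("a silent ChR2 unit emits only pulse-locked spikes at the follow rate", {
  spec <- neuron_spec("gpu1", "G_plus_unr", spontaneous_rate = 0,
                      follow_prob = 0.95)
  plan <- data.frame(stimulus = "SUC", light_condition = "control", n = 1)
  total <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    sim <- simulate_session(spec, panel5, plan, seed = s,
                            tag_frequencies = 10, tag_n_pulses = 100)
    total <- total + n_spikes(sim$spikes$gpu1)
  }
  # total pulse-locked spikes ~ Binomial(30 * 100, 0.95); 99% CI
  n <- n_seeds * 100
  expect_gt(total, n * 0.95 - 2.58 * sqrt(n * 0.95 * 0.05))
  expect_lt(total, n * 0.95 + 2.58 * sqrt(n * 0.95 * 0.05))
})

test_that("stimulus-window counts have the programmed Poisson mean", {
  spec <- neuron_spec("gm1", "G_minus_taste", spontaneous_rate = 3,
                      evoked_rate = c(SUC = 4))
  plan <- data.frame(stimulus = "SUC", light_condition = "control", n = 200)
  sim <- simulate_session(spec, panel5, plan, seed = 9,
                          tag_frequencies = numeric(0))
  counts <- mapply(count_spikes, onset = sim$trials$stim_onset_s,
                   duration = sim$trials$stim_dur_s,
                   MoreArgs = list(x = sim$spikes$gm1))
  # (3 + 4) Hz * 10 s = 70 expected; CI half-width ~ 2.58 * sqrt(70/200)
  expect_equal(mean(counts), 70, tolerance = 2.5 / 70)
})

test_that("gain 1 and offset 0 leave light-trial evoked rates unchanged", {
  spec <- neuron_spec("u", "G_minus_taste", spontaneous_rate = 2,
                      evoked_rate = c(SUC = 5), gain = 1, offset = 0)
  plan <- data.frame(stimulus = "SUC",
                     light_condition = c("control", "light_br"), n = 50)
  sim <- simulate_session(spec, panel5, plan, seed = 21,
                          tag_frequencies = numeric(0))
  ctrl <- net_response(sim$spikes$u, sim$trials, "SUC", "control")
  lt <- net_response(sim$spikes$u, sim$trials, "SUC", "light_br")
  expect_equal(ctrl$net_spikes_per_window, lt$net_spikes_per_window,
               tolerance = 6 / 50) # both estimate 50 net spikes
})

test_that("generated tables satisfy the core-data invariants", {
  specs <- population_specs(2, 1, 1, panel5, seed = 3)
  sim <- simulate_session(specs, panel5, trial_plan(panel5), seed = 3)
  expect_s3_class(taste_trials(as.data.frame(sim$trials)), "taste_trials")
  expect_s3_class(pulse_trains(as.data.frame(sim$pulses)), "pulse_trains")
  for (st in sim$spikes) {
    expect_false(is.unsorted(st$timestamps))
    expect_true(all(diff(st$timestamps) >= 0.001)) # refractory enforced
  }
})

test_that("mouth-light responses rise with frequency on the rising limb", {
  spec <- neuron_spec("u", "G_minus_taste", spontaneous_rate = 1,
                      evoked_rate = c(SUC = 0))
  sim <- simulate_lightm_series(spec, frequencies = c(2, 5, 10), seed = 2,
                                n_reps = 30, conditions = "control")
  nets <- vapply(c(2, 5, 10), function(f) {
    net_response(sim$spikes, sim$trials, sprintf("LM%g", f),
                 "control")$net_spikes_per_window
  }, double(1))
  expect_true(all(diff(nets) > 0))
  expect_error(simulate_lightm_series(spec, numeric(0), seed = 1), "empty")
})

test_that("a non-entrained unit shows only spontaneous activity to mouth light", {
  spec <- neuron_spec("u", "G_minus_taste", spontaneous_rate = 2)
  sim <- simulate_lightm_series(spec, frequencies = c(5, 20), seed = 6,
                                n_reps = 20, conditions = "control",
                                rate_fun = function(f) 0)
  for (f in c(5, 20)) {
    net <- net_response(sim$spikes, sim$trials, sprintf("LM%g", f), "control")
    expect_lt(abs(net$net_spikes_per_window), 1.5) # mean-zero net, 2-s windows
  }
  again <- simulate_lightm_series(spec, frequencies = c(5, 20), seed = 6,
                                  n_reps = 20, conditions = "control",
                                  rate_fun = function(f) 0)
  expect_identical(sim$spikes$timestamps, again$spikes$timestamps)
})

test_that("lick counts track access duration over the modal ILI", {
  # flat logistic at 1.0: every trial aims at SLR 1 => ~5 / 0.115 ~ 43 licks
  spec <- lick_spec("m1", modal_ili_ms = 115,
                    logistic_params = list(
                      saline = c(min = 1, max = 1, logec50 = 2, hill = 1),
                      CNO = c(min = 1, max = 1, logec50 = 2, hill = 1)),
                    slr_noise_sd = 0, pause_prob = 0)
  licks <- simulate_lick_study(spec, c(30, 100, 300, 1000), 5, seed = 8)
  per_trial <- tapply(!is.na(licks$lick_t_s),
                      paste(licks$drug, licks$trial_id), sum)
  expect_equal(mean(per_trial), 5 / 0.115, tolerance = 0.03)

  # min = max => lick ratio independent of concentration
  m <- lick_metrics(lick_table(licks), min_ilis = 50)
  by_conc <- tapply(m$slr, m$concentration, mean)
  expect_lt(diff(range(by_conc)), 0.05)
})
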