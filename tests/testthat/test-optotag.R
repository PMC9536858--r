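make_pulses <- function(onsets, hz = 10, train_id = "p1") {
  pulse_trains(data.frame(train_id = train_id, target = "brain",
                          light_condition = "light_br", nominal_hz = hz,
                          pulse_width_s = 0.005, onset_s = onsets))
}

test_that("constant-latency entrainment is recovered exactly from raw times", {
  onsets <- seq(1, by = 0.1, length.out = 20)
  # spikes 5.5 ms after 19 of 20 pulses
  st <- spike_train("u1", onsets[-7] + 0.0055, t_stop = 5)
  m <- pulse_metrics(st, make_pulses(onsets))
  expect_equal(m$follow_fraction, 0.95)
  expect_equal(m$latency_mean_ms, 5.5)
  expect_equal(m$latency_sd_ms, 0)
  expect_equal(m$n_pulses, 20)
})

test_that("latency mean and jitter match hand-computed sample statistics", {
  onsets <- seq(1, by = 0.1, length.out = 20)
  lat <- rep(c(0.005, 0.007), 10) # alternate 5 and 7 ms
  st <- spike_train("u1", onsets + lat, t_stop = 5)
  m <- pulse_metrics(st, make_pulses(onsets))
  expect_equal(m$latency_mean_ms, 6.0)
  expect_equal(m$latency_sd_ms, 1.025978, tolerance = 1e-6) # sd of 10x{5,7}
})

test_that("unfollowed trains are flagged, not errors; zero pulses do error", {
  onsets <- seq(1, by = 0.1, length.out = 20)
  st <- spike_train("u1", onsets + 0.05, t_stop = 5) # all outside 10-ms window
  m <- pulse_metrics(st, make_pulses(onsets))
  expect_equal(m$follow_fraction, 0)
  expect_true(is.na(m$latency_mean_ms))
  mouth_only <- make_pulses(onsets)
  mouth_only$target <- "mouth"
  expect_error(pulse_metrics(st, mouth_only), "no brain-light pulses")
})

test_that("following is invariant to spikes outside every search window", {
  onsets <- seq(1, by = 0.5, length.out = 10)
  inside <- onsets + 0.004
  m1 <- pulse_metrics(spike_train("u", inside, t_stop = 10),
                      make_pulses(onsets, hz = 2))
  outside <- sort(c(inside, onsets + 0.2, onsets - 0.1))
  m2 <- pulse_metrics(spike_train("u", outside, t_stop = 10),
                      make_pulses(onsets, hz = 2))
  expect_equal(m1$follow_fraction, m2$follow_fraction)
  expect_equal(m1$latency_mean_ms, m2$latency_mean_ms)
})

test_that("repeated trains at one frequency average; bursts count once", {
  onsets <- seq(1, by = 0.5, length.out = 10)
  p <- rbind(make_pulses(onsets, hz = 2, train_id = "a"),
             make_pulses(onsets + 20, hz = 2, train_id = "b"))
  # train a fully followed, train b half followed; doublets in train a
  ts <- sort(c(onsets + 0.004, onsets + 0.006, onsets[1:5] + 20 + 0.004))
  m <- pulse_metrics(spike_train("u", ts, t_stop = 40), pulse_trains(p))
  expect_equal(m$follow_fraction, (1 + 0.5) / 2)
  expect_equal(m$n_trains, 2)
  expect_equal(m$latency_mean_ms, 4) # first spike in window, both trains
})

test_that("classification uses the lowest frequency and the taste profile", {
  mk_metrics <- function(follow, lat, jit) {
    m <- data.frame(nominal_hz = c(1, 10), n_pulses = 20, n_trains = 1,
                    follow_fraction = c(follow, follow / 2),
                    latency_mean_ms = lat, latency_sd_ms = jit)
    class(m) <- c("optotag_metrics", class(m))
    attr(m, "unit_id") <- "u"
    m
  }
  sig_prof <- make_profile("u", c(0, 0, 0, 0, 30),
                           significant = c(rep(FALSE, 4), TRUE))
  uns_prof <- make_profile("u", c(0, 0, 0, 0, 0), significant = rep(FALSE, 5))

  # exemplar tagged taste cell: 96% follow, 5.9 +/- 0.72 ms
  cl <- classify_unit(mk_metrics(0.96, 5.9, 0.72), sig_prof)
  expect_equal(cl$class_label, "G_plus")
  expect_equal(cl$taste_class, "TASTE")
  # tagged but orally unresponsive: 88% follow, 5.8 +/- 0.68 ms
  cl <- classify_unit(mk_metrics(0.88, 5.8, 0.68), uns_prof)
  expect_equal(cl$class_label, "G_plus")
  expect_equal(cl$taste_class, "UNR")
  # taste cell suppressed by brain light, follow 0.05 -> non-GABA
  cl <- classify_unit(mk_metrics(0.05, 3.0, 1.0), sig_prof)
  expect_equal(cl$class_label, "G_minus")
  expect_equal(cl$taste_class, "TASTE")
  # mechanical flag wins over UNR when there is no taste response
  cl <- classify_unit(mk_metrics(0.9, 5, 0.5), NULL, mech_flag = TRUE)
  expect_equal(cl$taste_class, "MECH")
  # margins are signed distances to each threshold
  cl <- classify_unit(mk_metrics(0.96, 5.9, 0.72), sig_prof)
  expect_equal(unname(cl$margins["follow"]), 0.96 - 0.75)
  expect_equal(unname(cl$margins["jitter"]), 2 - 0.72)
})

test_that("simulated tagged and untagged units separate cleanly", {
  panel <- standard_panel("A")
  plan <- data.frame(stimulus = "SUC", light_condition = "control", n = 2)
  tagged <- neuron_spec("gp", "G_plus_unr", spontaneous_rate = 1)
  untagged <- neuron_spec("gm", "G_minus_taste", spontaneous_rate = 8,
                          evoked_rate = c(SUC = 4))
  sim <- simulate_session(list(tagged, untagged), panel, plan, seed = 12,
                          tag_frequencies = c(1, 10))
  m_gp <- pulse_metrics(sim$spikes$gp, sim$pulses)
  m_gm <- pulse_metrics(sim$spikes$gm, sim$pulses)
  expect_equal(classify_unit(m_gp)$class_label, "G_plus")
  expect_equal(classify_unit(m_gm)$class_label, "G_minus")
  expect_lte(m_gm$follow_fraction[m_gm$nominal_hz == 1], 0.2)
})
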