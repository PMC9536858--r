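# Shared fixtures and independent oracles for the test suite.

five_stimuli <- c("SUC", "MSGai", "NaCl", "CIT", "BIT")

# Build a response_profile directly from net-response vectors, bypassing
# spike counting, for tests of the downstream coding/gain stages.
make_profile <- function(unit_id, control, light = NULL,
                         stimuli = five_stimuli, significant = NULL,
                         baseline_sd = 1, n_trials = 2, window_s = 10) {
  mk <- function(vals, cond) {
    data.frame(unit_id = unit_id, stimulus = stimuli, light_condition = cond,
               net_spikes_per_window = vals, n_trials = n_trials,
               baseline_mean = 10, baseline_sd = baseline_sd,
               window_s = window_s)
  }
  df <- mk(control, "control")
  if (!is.null(light)) df <- rbind(df, mk(light, "light_br"))
  if (!is.null(significant)) df$significant <- significant
  structure(df, class = c("response_profile", class(df)),
            unit_id = unit_id,
            best_stimulus = c(control = stimuli[which.max(control)]),
            spontaneous_rate_hz = 1)
}

# Single-unit trial table with explicit windows.
make_trials <- function(n, stimulus = "SUC", light = "control",
                        prestim_dur = 10, stim_dur = 10, gap = 5) {
  step <- prestim_dur + stim_dur + gap
  taste_trials(data.frame(
    trial_id = sprintf("T%02d", seq_len(n)), stimulus = stimulus,
    stim_onset_s = (seq_len(n) - 1) * step + prestim_dur,
    stim_dur_s = stim_dur,
    prestim_onset_s = (seq_len(n) - 1) * step,
    prestim_dur_s = prestim_dur, light_condition = light
  ))
}

# Place `counts[i]` spikes uniformly inside window i = (onset, duration).
spikes_in_windows <- function(unit_id, onsets, durations, counts,
                              t_stop = NULL) {
  ts <- unlist(mapply(function(on, du, k) {
    if (k == 0) return(double())
    on + du * (seq_len(k) - 0.5) / k
  }, onsets, durations, counts, SIMPLIFY = FALSE))
  if (is.null(t_stop)) t_stop <- max(onsets + durations)
  spike_train(unit_id, sort(ts), t_stop = t_stop)
}

# Brute-force average-linkage agglomeration on a distance matrix: at each
# step merge the pair of clusters with the smallest mean inter-cluster
# distance. Returns merge heights in order.
avg_linkage_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- double()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Classical-scaling oracle: double-center the squared distances and
# eigendecompose.
cmds_oracle <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k)] %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
}

# Pearson r oracle written out from the definition.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
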