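# Optotagging: pulse-locked response metrics and classification of units
# into putative-GABA (G+) vs non-GABA (G-) classes, with the taste /
# unresponsive / mechanical sub-label.

#' Pulse-locked response metrics
#'
#' For each brain-light pulse, a 10-ms half-open search window
#' `[onset, onset + window)` is opened at pulse onset; the latency is the
#' time from onset to the first spike in the window (computed from raw
#' timestamps, so a constant simulated latency is recovered exactly), the
#' following fraction is the proportion of pulses with at least one spike
#' in the window (multiple spikes count once), and the jitter is the sample
#' SD of the latencies (defined only when at least two pulses were
#' followed). Metrics are computed per train and averaged across repeated
#' trains at the same nominal frequency.
#'
#' @param spikes A [spike_train].
#' @param pulses A [pulse_trains] table; only `target == "brain"` rows are
#'   used. Must contain at least one pulse.
#' @param window Search-window length, s (default 0.010).
#' @return Data frame of class `optotag_metrics`, one row per nominal
#'   frequency: `nominal_hz`, `n_pulses`, `n_trains`, `follow_fraction`,
#'   `latency_mean_ms` (NA when no pulse was followed), `latency_sd_ms`
#'   (jitter; NA when < 2 followed pulses).
#' @export
pulse_metrics <- function(spikes, pulses, window = 0.010) {
  stopifnot(inherits(spikes, "spike_train"))
  pulses <- pulses[pulses$target == "brain", , drop = FALSE]
  if ("unit_id" %in% names(pulses)) {
    pulses <- pulses[is.na(pulses$unit_id) | pulses$unit_id == spikes$unit_id, ,
                     drop = FALSE]
  }
  if (nrow(pulses) == 0) stop("no brain-light pulses supplied", call. = FALSE)
  ts <- spikes$timestamps

  per_train <- lapply(split(pulses, pulses$train_id), function(tr) {
    lat <- vapply(tr$onset_s, function(on) {
      i <- findInterval(on - 1e-12, ts) + 1L # first spike at or after onset
      if (i <= length(ts) && ts[i] < on + window) (ts[i] - on) * 1000 else NA_real_
    }, double(1))
    hit <- !is.na(lat)
    data.frame(
      nominal_hz = tr$nominal_hz[1],
      n_pulses = nrow(tr),
      follow_fraction = mean(hit),
      latency_mean_ms = if (any(hit)) mean(lat[hit]) else NA_real_,
      latency_sd_ms = if (sum(hit) >= 2) stats::sd(lat[hit]) else NA_real_
    )
  })
  tab <- do.call(rbind, per_train)
  out <- do.call(rbind, lapply(split(tab, tab$nominal_hz), function(g) {
    data.frame(
      nominal_hz = g$nominal_hz[1],
      n_pulses = sum(g$n_pulses),
      n_trains = nrow(g),
      follow_fraction = mean(g$follow_fraction),
      latency_mean_ms = if (all(is.na(g$latency_mean_ms))) NA_real_ else
        mean(g$latency_mean_ms, na.rm = TRUE),
      latency_sd_ms = if (all(is.na(g$latency_sd_ms))) NA_real_ else
        mean(g$latency_sd_ms, na.rm = TRUE)
    )
  }))
  out <- out[order(out$nominal_hz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("optotag_metrics", class(out))
  attr(out, "unit_id") <- spikes$unit_id
  attr(out, "window_s") <- window
  out
}

#' Classify a unit from its optotag metrics and taste profile
#'
#' A unit is labeled a putative GABA neuron (`G_plus`) when, at the lowest
#' tested pulse frequency, it followed at least `follow_min` of pulses with
#' mean latency at most `latency_max` ms and jitter at most `jitter_max`
#' ms; otherwise `G_minus`. Faithful low-frequency following is the
#' operative benchmark (tagged populations follow ~96% of 1-Hz pulses). The
#' taste sub-label is `TASTE` if any taste response passed the response
#' criterion, `MECH` if the unit was flagged as responsive to oral
#' mechanical stimulation, else `UNR`. No numeric thresholds are canonical
#' for the tag, so the defaults sit well clear of both the tagged (~0.96
#' following, jitter < 1 ms) and untagged (chance-level following)
#' distributions, and the margins to each threshold are reported.
#'
#' @param metrics An `optotag_metrics` table from [pulse_metrics()].
#' @param profile Optional flagged [response_profile] (see
#'   [flag_responses()]); absent for units never tested with taste.
#' @param mech_flag Was the unit responsive to oral mechanical stimulation?
#' @param follow_min,latency_max,jitter_max Classification thresholds
#'   (defaults 0.75, 10 ms, 2 ms).
#' @return List of class `optotag_class`: `unit_id`, `class_label`
#'   (`"G_plus"` / `"G_minus"`), `taste_class` (`"TASTE"` / `"UNR"` /
#'   `"MECH"`), the metrics row used, the thresholds, and `margins`
#'   (signed distance to each threshold; positive = clears it).
#' @export
classify_unit <- function(metrics, profile = NULL, mech_flag = FALSE,
                          follow_min = 0.75, latency_max = 10,
                          jitter_max = 2) {
  stopifnot(inherits(metrics, "optotag_metrics"), nrow(metrics) >= 1)
  row <- metrics[which.min(metrics$nominal_hz), , drop = FALSE]
  lat <- row$latency_mean_ms
  jit <- row$latency_sd_ms
  follow_ok <- row$follow_fraction >= follow_min
  lat_ok <- !is.na(lat) && lat <= latency_max
  jit_ok <- !is.na(jit) && jit <= jitter_max
  g_plus <- follow_ok && lat_ok && jit_ok

  tasted <- !is.null(profile) && "significant" %in% names(profile) &&
    any(profile$significant[profile$light_condition == "control"])
  taste_class <- if (tasted) "TASTE" else if (mech_flag) "MECH" else "UNR"

  structure(
    list(unit_id = attr(metrics, "unit_id"),
         class_label = if (g_plus) "G_plus" else "G_minus",
         taste_class = taste_class,
         tested_hz = row$nominal_hz,
         follow_fraction = row$follow_fraction,
         latency_mean_ms = lat, latency_sd_ms = jit,
         thresholds = c(follow_min = follow_min, latency_max = latency_max,
                        jitter_max = jitter_max),
         margins = c(follow = row$follow_fraction - follow_min,
                     latency = if (is.na(lat)) NA_real_ else latency_max - lat,
                     jitter = if (is.na(jit)) NA_real_ else jitter_max - jit)),
    class = "optotag_class"
  )
}

#' @export
print.optotag_class <- function(x, ...) {
  cat(sprintf(
    "<optotag_class> %s: %s / %s (follow %.2f at %g Hz, latency %.1f ms, jitter %s ms)\n",
    x$unit_id %||% "?", x$class_label, x$taste_class, x$follow_fraction,
    x$tested_hz, x$latency_mean_ms %||% NA,
    if (is.na(x$latency_sd_ms)) "NA" else sprintf("%.2f", x$latency_sd_ms)
  ))
  invisible(x)
}
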