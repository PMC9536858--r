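# Brief-access lick analysis: modal interlick interval, standardized lick
# ratio, water-relative quinine ratio, and the log-logistic
# concentration-response fit.

#' The log-logistic concentration-response equation
#'
#' `Y = min + (max - min) / (1 + 10^((logec50 - x) * hill))`, where `x` is
#' log10(concentration) and `Y` the standardized lick ratio. At
#' `x = logec50`, `Y = (min + max) / 2`.
#'
#' @param x Log10 concentration.
#' @param min,max Lower and upper asymptotes.
#' @param logec50 Log10 of the half-maximal concentration.
#' @param hill Hill slope (steepness; sign sets direction).
#' @return Predicted response.
#' @export
logistic_response <- function(x, min, max, logec50, hill) {
  min + (max - min) / (1 + 10^((logec50 - x) * hill))
}

.trial_ilis_ms <- function(licks) {
  key <- paste(licks$mouse_id, licks$session_id, licks$trial_id)
  unlist(lapply(split(licks$lick_t_s, key), function(tt) {
    tt <- tt[!is.na(tt)]
    if (length(tt) < 2) return(double())
    diff(tt) * 1000
  }), use.names = FALSE)
}

#' Modal interlick interval of a session
#'
#' The mode of the interlick-interval (ILI) histogram for one mouse and
#' session, restricted to a within-burst band (default 50-250 ms, which
#' excludes pauses and double-cranks), binned at `bin_ms` (default 5 ms);
#' the mode is the center of the tallest bin, ties broken toward the
#' smaller ILI (flagged). The modal ILI sets the maximum possible lick
#' count for the standardized lick ratio.
#'
#' @param licks A [lick_table] restricted to one mouse and session, or a
#'   numeric vector of ILIs in ms.
#' @param band Within-burst ILI band, ms.
#' @param bin_ms Histogram bin width, ms.
#' @param min_ilis Minimum number of in-band ILIs required (default 100).
#' @return Modal ILI in ms, with attribute `tie` (TRUE when the tallest bin
#'   was tied).
#' @export
modal_ili <- function(licks, band = c(50, 250), bin_ms = 5, min_ilis = 100) {
  ili <- if (is.numeric(licks)) licks else .trial_ilis_ms(licks)
  ili <- ili[ili >= band[1] & ili <= band[2]]
  if (length(ili) < min_ilis) {
    stop(sprintf("only %d in-band ILIs; need >= %d", length(ili), min_ilis),
         call. = FALSE)
  }
  edges <- seq(band[1], band[2] + bin_ms, by = bin_ms)
  counts <- graphics::hist(ili, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  top <- which(counts == max(counts))
  mode_ms <- edges[top[1]] + bin_ms / 2 # tie -> smaller ILI
  structure(mode_ms, tie = length(top) > 1)
}

#' Standardized lick ratio
#'
#' Licks emitted in a trial divided by the maximum possible licks in the
#' access window at the session's modal ILI: `SLR = licks /
#' (access_dur / modal_ili)`. Standardizing by the mouse-and-session modal
#' ILI compensates for drifts in lick rate across test sessions.
#'
#' @param n_licks Lick count(s).
#' @param access_dur Access duration, s.
#' @param modal_ili_ms Modal ILI, ms (> 0).
#' @return SLR value(s).
#' @examples
#' standardized_lick_ratio(30, 5, 125) # 0.75
#' @export
standardized_lick_ratio <- function(n_licks, access_dur, modal_ili_ms) {
  stopifnot(modal_ili_ms > 0, access_dur > 0)
  n_licks / (access_dur / (modal_ili_ms / 1000))
}

#' Water-relative lick ratio
#'
#' Mean licks to a tastant (quinine) at one concentration divided by the
#' session's mean licks to water — the appropriate standardization when
#' trials are run under water deprivation and the stimulus suppresses
#' licking below the water rate.
#'
#' @param tastant_licks Per-trial lick counts at one concentration.
#' @param water_licks Per-trial lick counts on the session's water trials
#'   (>= 1 trial required).
#' @return Ratio; `NA` with attribute `undefined = TRUE` when the water
#'   mean is zero.
#' @export
water_ratio <- function(tastant_licks, water_licks) {
  if (!length(water_licks)) stop("no water trials in session", call. = FALSE)
  w <- mean(water_licks)
  if (w == 0) return(structure(NA_real_, undefined = TRUE))
  mean(tastant_licks) / w
}

#' Per-session lick metrics
#'
#' Computes, for every mouse x session in a [lick_table]: the modal ILI,
#' per-trial lick counts and standardized lick ratios, and per-concentration
#' means. Mice that sampled any tested concentration on fewer than
#' `min_trials` trials in a session are excluded, and the exclusions are
#' reported in the `excluded` attribute (and as messages). When the session
#' contains water trials, the water-relative ratio is reported alongside
#' the SLR.
#'
#' @param licks A [lick_table].
#' @param min_trials Minimum trials per concentration per session
#'   (default 2).
#' @param band,bin_ms,min_ilis Passed to [modal_ili()].
#' @return Data frame of class `lick_metrics`: `mouse_id`, `session_id`,
#'   `drug`, `stimulus`, `concentration`, `n_trials`, `mean_licks`, `slr`,
#'   `water_ratio` (NA when no water trials), `modal_ili_ms`.
#' @export
lick_metrics <- function(licks, min_trials = 2, band = c(50, 250),
                         bin_ms = 5, min_ilis = 100) {
  stopifnot(inherits(licks, "lick_table"))
  excluded <- character()
  out <- list()
  for (ms in split(licks, paste(licks$mouse_id, licks$session_id, sep = "|"))) {
    mouse <- ms$mouse_id[1]
    sess <- ms$session_id[1]
    per_trial <- do.call(rbind, lapply(split(ms, ms$trial_id), function(tr) {
      data.frame(stimulus = tr$stimulus[1], concentration = tr$concentration[1],
                 access_dur_s = tr$access_dur_s[1],
                 n_licks = sum(!is.na(tr$lick_t_s)))
    }))
    tasted <- per_trial[per_trial$stimulus != "WATER", , drop = FALSE]
    n_per_conc <- table(paste(tasted$stimulus, tasted$concentration))
    if (any(n_per_conc < min_trials)) {
      excluded <- c(excluded, paste(mouse, sess, sep = "/"))
      message("excluding mouse/session ", mouse, "/", sess,
              ": fewer than ", min_trials, " trials for some concentration")
      next
    }
    ili <- modal_ili(ms, band = band, bin_ms = bin_ms, min_ilis = min_ilis)
    water <- per_trial$n_licks[per_trial$stimulus == "WATER"]
    key <- paste(per_trial$stimulus, per_trial$concentration)
    for (g in split(tasted, paste(tasted$stimulus, tasted$concentration))) {
      out[[length(out) + 1L]] <- data.frame(
        mouse_id = mouse, session_id = sess, drug = ms$drug[1],
        stimulus = g$stimulus[1], concentration = g$concentration[1],
        n_trials = nrow(g), mean_licks = mean(g$n_licks),
        slr = mean(standardized_lick_ratio(g$n_licks, g$access_dur_s,
                                           as.numeric(ili))),
        water_ratio = if (length(water)) {
          as.numeric(water_ratio(g$n_licks, water))
        } else NA_real_,
        modal_ili_ms = as.numeric(ili)
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(mouse_id = character(), session_id = character(),
               drug = character(), stimulus = character(),
               concentration = double(), n_trials = integer(),
               mean_licks = double(), slr = double(),
               water_ratio = double(), modal_ili_ms = double())
  }
  class(res) <- c("lick_metrics", class(res))
  attr(res, "excluded") <- excluded
  res
}

#' Fit the log-logistic concentration-response curve
#'
#' Nonlinear least squares on `Y = min + (max - min) / (1 +
#' 10^((logec50 - x) * hill))` with `x = log10(concentration)`.
#' Initialization is multi-start — asymptotes from the data extremes, a
#' LogEC50 grid across the tested range, Hill slopes in {±0.5, ±1, ±2} —
#' and the converged fit with the lowest residual sum of squares is kept.
#' When no start converges (as happens for response patterns with no
#' sigmoid shape), the fit is returned with `converged = FALSE` rather than
#' raising.
#'
#' @param concentrations Numeric concentrations (>= 4 distinct values); or
#'   already-logged values with `log10_x = FALSE`.
#' @param responses Matched mean responses (e.g., SLR per concentration).
#' @param log10_x Take log10 of `concentrations` (default TRUE)?
#' @return List of class `logistic_fit`: `min`, `max`, `logec50`, `hill`,
#'   `ec50` (`10^logec50`, concentration units), `converged`, `rss`, `n`,
#'   `fitted`.
#' @export
fit_logistic <- function(concentrations, responses, log10_x = TRUE) {
  if (length(unique(concentrations)) < 4) {
    stop("need >= 4 distinct concentrations", call. = FALSE)
  }
  stopifnot(length(concentrations) == length(responses))
  x <- if (log10_x) log10(concentrations) else concentrations
  y <- responses
  rng <- range(x)
  starts <- expand.grid(
    logec50 = seq(rng[1], rng[2], length.out = 5),
    hill = c(-2, -1, -0.5, 0.5, 1, 2),
    KEEP.OUT.ATTRS = FALSE
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ logistic_response(x, mn, mx, le, hl),
        start = list(mn = min(y), mx = max(y),
                     le = starts$logec50[i], hl = starts$hill[i]),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(min = NA_real_, max = NA_real_, logec50 = NA_real_,
           hill = NA_real_, ec50 = NA_real_, converged = FALSE,
           rss = NA_real_, n = length(y), fitted = NULL),
      class = "logistic_fit"
    ))
  }
  cf <- stats::coef(best$fit)
  # report with min <= max (flipping both asymptotes and the Hill sign
  # leaves the curve unchanged)
  mn <- unname(cf["mn"]); mx <- unname(cf["mx"]); hl <- unname(cf["hl"])
  if (mn > mx) {
    tmp <- mn; mn <- mx; mx <- tmp; hl <- -hl
  }
  structure(
    list(min = mn, max = mx, logec50 = unname(cf["le"]), hill = hl,
         ec50 = 10^unname(cf["le"]), converged = TRUE, rss = best$rss,
         n = length(y), fitted = stats::fitted(best$fit)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<logistic_fit> did not converge\n")
  } else {
    cat(sprintf(
      "<logistic_fit> min %.3f, max %.3f, EC50 %.4g (logEC50 %.3f), Hill %.2f; rss %.4g\n",
      x$min, x$max, x$ec50, x$logec50, x$hill, x$rss
    ))
  }
  invisible(x)
}

#' Bonferroni-adjusted paired comparisons across concentrations
#'
#' Orchestration around [stats::t.test()] and [stats::p.adjust()]: pairs
#' each mouse's saline and CNO values at every concentration, runs paired t
#' tests, and Bonferroni-adjusts across concentrations. The tests
#' themselves are standard routines; only the pairing and adjustment are
#' performed here.
#'
#' @param metrics A [lick_metrics] data frame (or any data frame with
#'   `mouse_id`, `drug`, `concentration` and the value column).
#' @param value Name of the value column (default `"slr"`).
#' @return Data frame: `concentration`, `n_pairs`, `mean_saline`,
#'   `mean_cno`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
paired_concentration_tests <- function(metrics, value = "slr") {
  stopifnot(value %in% names(metrics))
  rows <- lapply(split(metrics, metrics$concentration), function(g) {
    sal <- g[g$drug == "saline", ]
    cno <- g[g$drug == "CNO", ]
    mice <- intersect(sal$mouse_id, cno$mouse_id)
    v1 <- vapply(mice, function(m) mean(sal[[value]][sal$mouse_id == m]), double(1))
    v2 <- vapply(mice, function(m) mean(cno[[value]][cno$mouse_id == m]), double(1))
    if (length(mice) < 2) {
      return(data.frame(concentration = g$concentration[1],
                        n_pairs = length(mice), mean_saline = mean(v1),
                        mean_cno = mean(v2), t = NA_real_, df = NA_real_,
                        p = NA_real_))
    }
    tt <- stats::t.test(v1, v2, paired = TRUE)
    data.frame(concentration = g$concentration[1], n_pairs = length(mice),
               mean_saline = mean(v1), mean_cno = mean(v2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration), , drop = FALSE]
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}
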