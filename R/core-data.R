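#' gustnet: gustatory spike-train analysis under optogenetic inhibition
#'
#' Analysis of taste-evoked responses in rostral nucleus of the solitary
#' tract (rNST) neurons recorded with and without activation of the local
#' GABA network, plus brief-access licking behavior. The package covers the
#' full chain: trial-aligned net responses and a joint response criterion,
#' optotag metrics and cell classification, breadth-of-tuning measures,
#' chemosensitive clustering and ensemble multidimensional scaling,
#' threshold-linear divisive/subtractive gain decomposition, lick
#' microstructure with logistic concentration-response fits, and a
#' ground-truth synthetic generator used for validation throughout.
#'
#' @keywords internal
#' @aliases gustnet-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain types. All times are seconds from session start, as plain doubles.
# ---------------------------------------------------------------------------

#' Construct a spike train
#'
#' A spike train holds the action-potential timestamps of one isolated unit
#' for one recording session. Timestamps must be finite, nonnegative and
#' nondecreasing; unsorted input is an error in the constructor (the file
#' readers sort for you).
#'
#' @param unit_id Character scalar identifying the unit.
#' @param timestamps Numeric vector of spike times in seconds.
#' @param t_stop Optional recording-end time (seconds). Defaults to the last
#'   spike time (or 0 for an empty train). Used to detect analysis windows
#'   that fall outside the recorded span.
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train("u1", c(0.2, 0.5, 1.1))
#' n_spikes(st)
#' @export
spike_train <- function(unit_id, timestamps, t_stop = NULL) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L, nzchar(unit_id))
  timestamps <- as.double(timestamps)
  if (anyNA(timestamps) || any(!is.finite(timestamps))) {
    stop("spike timestamps must be finite", call. = FALSE)
  }
  if (any(timestamps < 0)) {
    stop("spike timestamps must be >= 0", call. = FALSE)
  }
  if (is.unsorted(timestamps)) {
    stop("spike timestamps must be nondecreasing", call. = FALSE)
  }
  if (is.null(t_stop)) {
    t_stop <- if (length(timestamps)) timestamps[length(timestamps)] else 0
  }
  structure(
    list(unit_id = unit_id, timestamps = timestamps, t_stop = as.double(t_stop)),
    class = "spike_train"
  )
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$timestamps)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> unit %s: %d spikes over %.1f s\n",
    x$unit_id, length(x$timestamps), x$t_stop
  ))
  invisible(x)
}

#' Count spikes of a train inside a half-open window
#'
#' @param x A `spike_train`.
#' @param onset,duration Window start and length in seconds; the window is
#'   `[onset, onset + duration)`.
#' @return Integer spike count.
#' @export
count_spikes <- function(x, onset, duration) {
  stopifnot(inherits(x, "spike_train"), duration > 0)
  ts <- x$timestamps
  sum(ts >= onset & ts < onset + duration)
}

.light_conditions <- c("control", "light_br")

#' Construct / validate a taste-trial table
#'
#' Each row is one stimulus delivery: the stimulus label, the onset and
#' duration of the stimulus window (default 10 s), the matched prestimulus
#' artificial-saliva window (default 10 s, ending at or before stimulus
#' onset), and the light condition (`control` or `light_br`, concurrent
#' brain-light activation of the GABA network). Trials carry their own
#' prestimulus window explicitly, so irregular inter-trial intervals need no
#' reconstruction.
#'
#' @param df A data frame with columns `trial_id`, `stimulus`,
#'   `stim_onset_s`, `stim_dur_s`, `prestim_onset_s`, `prestim_dur_s`,
#'   `light_condition`; an optional `unit_id` column restricts trials to one
#'   unit.
#' @return The validated data frame with class `taste_trials`.
#' @export
taste_trials <- function(df) {
  req <- c("trial_id", "stimulus", "stim_onset_s", "stim_dur_s",
           "prestim_onset_s", "prestim_dur_s", "light_condition")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("stim_onset_s", "stim_dur_s", "prestim_onset_s", "prestim_dur_s")
  for (col in num) {
    df[[col]] <- as.double(df[[col]])
    if (anyNA(df[[col]])) stop("non-numeric value in ", col, call. = FALSE)
  }
  if (any(df$stim_dur_s <= 0) || any(df$prestim_dur_s <= 0)) {
    stop("trial durations must be > 0", call. = FALSE)
  }
  bad <- which(df$prestim_onset_s + df$prestim_dur_s > df$stim_onset_s + 1e-9)
  if (length(bad)) {
    stop(sprintf(
      "prestimulus window overlaps the stimulus window for trial %s",
      df$trial_id[bad[1]]
    ), call. = FALSE)
  }
  if (!all(df$light_condition %in% .light_conditions)) {
    bad <- setdiff(unique(df$light_condition), .light_conditions)
    stop("unknown light_condition: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- unique(c("taste_trials", class(df)))
  df
}

#' Construct / validate a pulse-train table
#'
#' One row per light pulse. `target` distinguishes brain light (activates
#' the GABA network through the optrode) from mouth light (drives
#' ChR2-expressing taste-bud cells, a graded surrogate taste stimulus); for
#' mouth-light trains the `light_condition` records whether brain light was
#' delivered concurrently. Onsets must be strictly increasing within a
#' train.
#'
#' @param df Data frame with columns `train_id`, `target`,
#'   `light_condition`, `nominal_hz`, `pulse_width_s`, `onset_s` and an
#'   optional `unit_id`.
#' @return Validated data frame of class `pulse_trains`.
#' @export
pulse_trains <- function(df) {
  req <- c("train_id", "target", "light_condition", "nominal_hz",
           "pulse_width_s", "onset_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("pulse table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("nominal_hz", "pulse_width_s", "onset_s")) {
    df[[col]] <- as.double(df[[col]])
    if (anyNA(df[[col]])) stop("non-numeric value in ", col, call. = FALSE)
  }
  if (any(df$pulse_width_s <= 0)) stop("pulse_width_s must be > 0", call. = FALSE)
  if (!all(df$target %in% c("brain", "mouth"))) {
    stop("pulse target must be 'brain' or 'mouth'", call. = FALSE)
  }
  if (!all(df$light_condition %in% .light_conditions)) {
    stop("unknown light_condition in pulse table", call. = FALSE)
  }
  for (id in unique(df$train_id)) {
    on <- df$onset_s[df$train_id == id]
    if (any(diff(on) <= 0)) {
      stop("pulse onsets must be strictly increasing within train ", id,
           call. = FALSE)
    }
  }
  class(df) <- unique(c("pulse_trains", class(df)))
  df
}

#' Stimulus panels
#'
#' A stimulus panel fixes the ordered set of taste stimuli, their
#' concentrations, and which stimuli are excluded from the noise:signal
#' breadth measure. The umami stimulus MSGai is excluded from N:S by default
#' because at high concentration it co-activates sugar/umami cells and
#' amiloride-insensitive sodium cells, making a second-best/best ratio
#' against it uninterpretable. Panel order is also the documented tie-break
#' for best-stimulus and ordering decisions.
#'
#' @param stimuli Character vector of stimulus labels, in panel order.
#' @param concentrations Optional numeric vector (same length) of
#'   concentrations; units are the caller's.
#' @param exclude_from_ns Character vector of labels excluded from the N:S
#'   ratio.
#' @return Object of class `stimulus_panel`.
#' @examples
#' standard_panel("A")
#' @export
stimulus_panel <- function(stimuli, concentrations = NULL,
                           exclude_from_ns = intersect("MSGai", stimuli)) {
  stimuli <- as.character(stimuli)
  if (length(stimuli) < 2L) stop("a panel needs >= 2 stimuli", call. = FALSE)
  if (anyDuplicated(stimuli)) stop("duplicated stimulus labels", call. = FALSE)
  if (!is.null(concentrations) && length(concentrations) != length(stimuli)) {
    stop("concentrations must match stimuli", call. = FALSE)
  }
  if (!all(exclude_from_ns %in% stimuli)) {
    stop("exclude_from_ns labels not in panel", call. = FALSE)
  }
  structure(
    list(stimuli = stimuli, concentrations = concentrations,
         exclude_from_ns = exclude_from_ns),
    class = "stimulus_panel"
  )
}

#' @rdname stimulus_panel
#' @param set `"A"` (mid-high concentrations: 600 mM sucrose, 600 mM MSGai,
#'   300 mM NaCl, 30 mM citric acid, cycloheximide + quinine bitter mix) or
#'   `"B"` (mid-range concentrations).
#' @export
standard_panel <- function(set = c("A", "B")) {
  set <- match.arg(set)
  conc <- if (set == "A") c(600, 600, 300, 30, 2.71) else c(300, 600, 100, 10, 0.01)
  stimulus_panel(c("SUC", "MSGai", "NaCl", "CIT", "BIT"), conc)
}

#' Construct / validate a lick table for brief-access sessions
#'
#' One row per lick (rows with `lick_t_s = NA` stand for a sampled trial
#' with zero licks). Trials are 5-s access windows timed from the first
#' lick, as in a Davis-rig brief-access test; `drug` records the saline /
#' CNO injection condition of the session.
#'
#' @param df Data frame with columns `mouse_id`, `session_id`, `drug`,
#'   `trial_id`, `stimulus`, `concentration`, `conc_units`, `access_dur_s`,
#'   `lick_t_s`.
#' @return Validated data frame of class `lick_table`.
#' @export
lick_table <- function(df) {
  req <- c("mouse_id", "session_id", "drug", "trial_id", "stimulus",
           "concentration", "conc_units", "access_dur_s", "lick_t_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("lick table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$access_dur_s <- as.double(df$access_dur_s)
  df$lick_t_s <- as.double(df$lick_t_s)
  df$concentration <- as.double(df$concentration)
  if (any(df$access_dur_s <= 0)) stop("access_dur_s must be > 0", call. = FALSE)
  if (!all(df$drug %in% c("saline", "CNO"))) {
    stop("drug must be 'saline' or 'CNO'", call. = FALSE)
  }
  key <- paste(df$mouse_id, df$session_id, df$trial_id)
  for (k in unique(key)) {
    tt <- df$lick_t_s[key == k]
    tt <- tt[!is.na(tt)]
    if (length(tt) && (is.unsorted(tt) || any(tt < 0))) {
      stop("lick timestamps must be nonnegative and nondecreasing in trial ",
           k, call. = FALSE)
    }
  }
  class(df) <- unique(c("lick_table", class(df)))
  df
}
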