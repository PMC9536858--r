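# Delimited-text readers and writers for the four table formats, plus JSON
# sidecar metadata. All files are plain CSV with a header row; times are
# seconds as decimal numbers.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && length(names(df)) == 0) {
    return(NULL) # entirely empty file
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

.check_numeric_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.double(raw))
  bad <- which(is.na(val) & !(allow_na & (is.na(raw) | raw == "")))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric %s at data line %d ('%s')",
                 basename(path), col, bad[1], as.character(raw[bad[1]])),
         call. = FALSE)
  }
  val
}

#' Read and write spike tables
#'
#' `read_spikes()` reads a CSV with columns `unit_id,t_seconds` and returns
#' a named list of [spike_train] objects (one per unit, timestamps sorted).
#' An empty file yields an empty collection. `write_spikes()` writes the
#' inverse format; the pair round-trips losslessly up to row order.
#'
#' @param path File path.
#' @return `read_spikes()`: named list of `spike_train`.
#' @export
read_spikes <- function(path) {
  df <- .read_csv_checked(path, c("unit_id", "t_seconds"))
  if (is.null(df) || nrow(df) == 0) {
    out <- list()
    class(out) <- "spike_train_list"
    return(out)
  }
  tt <- .check_numeric_col(df, "t_seconds", path)
  bad <- which(tt < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative spike time at data line %d", basename(path),
                 bad[1]), call. = FALSE)
  }
  out <- lapply(split(tt, df$unit_id), function(x) NULL)
  for (uid in names(out)) {
    out[[uid]] <- spike_train(uid, sort(tt[df$unit_id == uid]))
  }
  class(out) <- "spike_train_list"
  out
}

#' @rdname read_spikes
#' @param spikes A `spike_train`, or a (possibly named) list of them.
#' @export
write_spikes <- function(spikes, path) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  rows <- lapply(spikes, function(st) {
    if (length(st$timestamps) == 0) return(NULL)
    data.frame(unit_id = st$unit_id, t_seconds = st$timestamps)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(unit_id = character(), t_seconds = double())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trial, pulse and lick tables
#'
#' Thin CSV readers that validate through the corresponding constructors
#' ([taste_trials], [pulse_trains], [lick_table]), so every object handed to
#' the analysis satisfies the stated invariants.
#'
#' @param path File path.
#' @return The validated table.
#' @export
read_trials <- function(path) {
  df <- .read_csv_checked(path, c("trial_id", "stimulus", "stim_onset_s",
                                  "stim_dur_s", "prestim_onset_s",
                                  "prestim_dur_s", "light_condition"))
  if (is.null(df)) stop(basename(path), ": empty trial file", call. = FALSE)
  for (col in c("stim_onset_s", "stim_dur_s", "prestim_onset_s", "prestim_dur_s")) {
    df[[col]] <- .check_numeric_col(df, col, path)
  }
  taste_trials(df)
}

#' @rdname read_trials
#' @param trials A `taste_trials` table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_pulses <- function(path) {
  df <- .read_csv_checked(path, c("train_id", "target", "light_condition",
                                  "nominal_hz", "pulse_width_s", "onset_s"))
  if (is.null(df)) stop(basename(path), ": empty pulse file", call. = FALSE)
  for (col in c("nominal_hz", "pulse_width_s", "onset_s")) {
    df[[col]] <- .check_numeric_col(df, col, path)
  }
  pulse_trains(df)
}

#' @rdname read_trials
#' @param pulses A `pulse_trains` table.
#' @export
write_pulses <- function(pulses, path) {
  utils::write.csv(as.data.frame(pulses), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_licks <- function(path) {
  df <- .read_csv_checked(path, c("mouse_id", "session_id", "drug", "trial_id",
                                  "stimulus", "concentration", "conc_units",
                                  "access_dur_s", "lick_t_s"))
  if (is.null(df)) stop(basename(path), ": empty lick file", call. = FALSE)
  df$concentration <- .check_numeric_col(df, "concentration", path)
  df$access_dur_s <- .check_numeric_col(df, "access_dur_s", path)
  df$lick_t_s <- .check_numeric_col(df, "lick_t_s", path, allow_na = TRUE)
  lick_table(df)
}

#' @rdname read_trials
#' @param licks A `lick_table`.
#' @export
write_licks <- function(licks, path) {
  utils::write.csv(as.data.frame(licks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a JSON sidecar (panel definition and session metadata)
#'
#' @param path File path of the `.json` sidecar.
#' @return `read_sidecar()`: a list; panels found under `$panel` are
#'   reconstructed as [stimulus_panel] objects.
#' @export
read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(meta$panel)) {
    meta$panel <- stimulus_panel(
      meta$panel$stimuli,
      meta$panel$concentrations,
      exclude_from_ns = meta$panel$exclude_from_ns %||% character()
    )
  }
  meta
}

#' @rdname read_sidecar
#' @param meta List of metadata; a [stimulus_panel] under `$panel` is
#'   serialized by its fields.
#' @export
write_sidecar <- function(meta, path) {
  if (!is.null(meta$panel) && inherits(meta$panel, "stimulus_panel")) {
    meta$panel <- unclass(meta$panel)
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
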