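#' Construct a trial record
#'
#' One pointing trial: the participant is prompted, reaches out and
#' touches the target, optionally hears a tone delayed by 0.1, 0.4 or
#' 0.7 s after the touch, and (in the time-estimation task) reports the
#' perceived delay on a 0-1 sliding scale. Event times must be
#' non-decreasing in the order prompt <= touch <= tone <= response, and
#' when both `tone` and `tone_delay` are present they must agree within
#' one sample at `fs`.
#'
#' @param trial_index integer >= 0.
#' @param condition condition label (e.g. `"control"`, `"low_load"`,
#'   `"high_load"`, `"time_estimation"`).
#' @param event_times named list/vector with any of `prompt`, `touch`,
#'   `tone`, `response`, in seconds on the session clock.
#' @param tone_delay tone onset delay after touch, seconds, or `NA`.
#' @param response_value slider response in `[0, 1]`, or `NA`.
#' @param fs sampling rate used for the one-sample consistency check.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(trial_index, condition, event_times,
                         tone_delay = NA_real_, response_value = NA_real_,
                         fs = 240) {
  stopifnot(trial_index >= 0)
  ev <- as.list(event_times)
  known <- c("prompt", "touch", "tone", "response")
  if (!all(names(ev) %in% known))
    stop("unknown event name(s): ",
         paste(setdiff(names(ev), known), collapse = ", "), call. = FALSE)
  ordered <- unlist(ev[known[known %in% names(ev)]])
  if (any(diff(ordered) < 0))
    stop("event times must be non-decreasing in the order prompt <= touch <= tone <= response",
         call. = FALSE)
  if (!is.na(tone_delay) && all(c("touch", "tone") %in% names(ev))) {
    if (abs((ev$tone - ev$touch) - tone_delay) > 1 / fs)
      stop("tone - touch must equal tone_delay within one sample", call. = FALSE)
  }
  if (!is.na(response_value) && (response_value < 0 || response_value > 1))
    stop("response_value must lie in [0, 1]", call. = FALSE)
  structure(
    list(trial_index = as.integer(trial_index),
         condition = as.character(condition),
         event_times = lapply(ev, as.numeric),
         tone_delay = as.numeric(tone_delay),
         response_value = as.numeric(response_value)),
    class = "trial_record"
  )
}

#' Construct a session record
#'
#' A participant x condition block of trials together with the
#' continuously recorded channels (kinematics, angular rate, ECG, ...).
#' All trial event times must lie within the time range of every
#' channel.
#'
#' @param participant_id label.
#' @param condition condition label.
#' @param trials list of [trial_record()] objects (>= 1).
#' @param channels named list of [timeseries()] objects.
#' @return An object of class `"session_record"`.
#' @export
session_record <- function(participant_id, condition, trials, channels) {
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "trial_record")),
            all(vapply(channels, inherits, logical(1), "timeseries")))
  ev <- unlist(lapply(trials, function(tr) unlist(tr$event_times)))
  if (length(ev) && length(channels)) {
    for (ch in channels) {
      if (min(ev) < ch$t[1] - 1e-9 || max(ev) > ch$t[length(ch$t)] + 1e-9)
        stop(sprintf("trial event times fall outside channel '%s' time range",
                     ch$channel_id), call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         condition = as.character(condition),
         trials = trials, channels = channels),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session %s/%s: %d trials, channels: %s>\n",
              x$participant_id, x$condition, length(x$trials),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a trial-event table
#'
#' CSV with columns `trial`, `condition`, `t_prompt`, `t_touch`,
#' `t_tone`, `t_response`, `tone_delay`, `response_value` (event and
#' response columns may hold NA).
#'
#' @param path path to the events CSV.
#' @param fs sampling rate for the tone-delay consistency check.
#' @return List of [trial_record()] objects.
#' @export
read_events_csv <- function(path, fs = 240) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("trial", "condition")
  if (!all(need %in% names(df)))
    stop("format error: events table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ev <- list()
    for (nm in c("prompt", "touch", "tone", "response")) {
      col <- paste0("t_", nm)
      if (col %in% names(df) && is.finite(row[[col]])) ev[[nm]] <- row[[col]]
    }
    trial_record(row$trial, row$condition, ev,
                 tone_delay = if ("tone_delay" %in% names(df))
                   row$tone_delay else NA_real_,
                 response_value = if ("response_value" %in% names(df))
                   row$response_value else NA_real_,
                 fs = fs)
  })
}

#' Write a trial-event table
#'
#' @param trials list of [trial_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(trials, path) {
  get_ev <- function(tr, nm)
    if (!is.null(tr$event_times[[nm]])) tr$event_times[[nm]] else NA_real_
  df <- data.frame(
    trial = vapply(trials, function(tr) tr$trial_index, integer(1)),
    condition = vapply(trials, function(tr) tr$condition, character(1)),
    t_prompt = vapply(trials, get_ev, numeric(1), "prompt"),
    t_touch = vapply(trials, get_ev, numeric(1), "touch"),
    t_tone = vapply(trials, get_ev, numeric(1), "tone"),
    t_response = vapply(trials, get_ev, numeric(1), "response"),
    tone_delay = vapply(trials, function(tr) tr$tone_delay, numeric(1)),
    response_value = vapply(trials, function(tr) tr$response_value, numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a session to a directory of CSV files
#'
#' Writes one CSV per channel (`<channel_id>.csv`) and an
#' `events.csv` trial table, the same schemas [read_session_csv()]
#' reads back.
#'
#' @param session a [session_record()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(session$channels))
    write_timeseries_csv(session$channels[[nm]], file.path(dir, paste0(nm, ".csv")))
  write_events_csv(session$trials, file.path(dir, "events.csv"))
  meta <- list(participant_id = session$participant_id,
               condition = session$condition,
               channels = lapply(session$channels, function(ch)
                 list(fs = ch$fs, units = ch$units)))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from a directory written by [write_session_csv()]
#'
#' @param dir session directory.
#' @return A [session_record()].
#' @export
read_session_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  channels <- lapply(names(meta$channels), function(nm) {
    read_timeseries_csv(file.path(dir, paste0(nm, ".csv")),
                        units = meta$channels[[nm]]$units, channel_id = nm)
  })
  names(channels) <- names(meta$channels)
  fs0 <- if (length(channels)) channels[[1]]$fs else 240
  trials <- read_events_csv(file.path(dir, "events.csv"), fs = fs0)
  session_record(meta$participant_id, meta$condition, trials, channels)
}
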