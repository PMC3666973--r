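# Event-table I/O and the three exclusion rules applied before feature
# extraction: long fixations, blink-adjacent events, and search trials on
# which the target was found. All filters are row subsets of the event
# table -- no event is ever modified -- so they are idempotent, order
# preserving, and commute with one another.

.event_columns <- c("participant", "session", "task", "trial", "event_index",
                    "event_type", "duration_ms", "amplitude_deg",
                    "blink_before", "blink_after", "target_present",
                    "target_found")

#' Read a fixation-report event table
#'
#' Reads the CSV dialect used throughout the pipeline: UTF-8, header row,
#' columns exactly `participant, session, task, trial, event_index,
#' event_type, duration_ms, amplitude_deg, blink_before, blink_after,
#' target_present, target_found`, with empty strings for inapplicable
#' fields (amplitude on fixation rows, duration on saccade rows, target
#' flags outside search trials).
#'
#' @param path CSV file path.
#' @return Event table data.frame.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_event_table: no such file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(.event_columns, names(raw))
  if (length(missing))
    stop(sprintf("read_event_table: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  raw <- raw[.event_columns]
  out <- data.frame(
    participant = raw$participant,
    session = raw$session,
    task = raw$task,
    trial = as.integer(raw$trial),
    event_index = as.integer(raw$event_index),
    event_type = raw$event_type,
    duration_ms = suppressWarnings(as.numeric(raw$duration_ms)),
    amplitude_deg = suppressWarnings(as.numeric(raw$amplitude_deg)),
    blink_before = raw$blink_before == "TRUE",
    blink_after = raw$blink_after == "TRUE",
    target_present = ifelse(raw$target_present == "", NA,
                            raw$target_present == "TRUE"),
    target_found = ifelse(raw$target_found == "", NA,
                          raw$target_found == "TRUE"),
    stringsAsFactors = FALSE
  )
  bad_type <- which(!out$event_type %in% c("fixation", "saccade"))
  if (length(bad_type))
    stop(sprintf("read_event_table: unknown event_type at row(s): %s",
                 paste(utils::head(bad_type, 10), collapse = ", ")),
         call. = FALSE)
  bad_fix <- which(out$event_type == "fixation" &
                     (is.na(out$duration_ms) | !is.na(out$amplitude_deg)))
  bad_sacc <- which(out$event_type == "saccade" &
                      (is.na(out$amplitude_deg) | !is.na(out$duration_ms)))
  bad <- sort(c(bad_fix, bad_sacc))
  if (length(bad))
    stop(sprintf(paste0("read_event_table: inconsistent event fields ",
                        "(fixations need duration only, saccades amplitude ",
                        "only) at row(s): %s"),
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  out
}

#' Write a fixation-report event table
#'
#' Inverse of [read_event_table()]: writes the same CSV dialect, with
#' empty strings for inapplicable fields.
#'
#' @param events Event table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(all(.event_columns %in% names(events)))
  utils::write.csv(events[.event_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove over-long fixations
#'
#' Drops fixation rows strictly longer than `max_ms` (the conventional
#' artifact cutoff is 1500 ms). The comparison is strict: a fixation of
#' exactly `max_ms` is retained. Saccades are untouched and row order is
#' preserved.
#'
#' @param events Event table.
#' @param max_ms Cutoff in ms (default 1500).
#' @return Filtered event table.
#' @export
filter_long_fixations <- function(events, max_ms = 1500) {
  drop <- events$event_type == "fixation" &
    !is.na(events$duration_ms) & events$duration_ms > max_ms
  events[!drop, , drop = FALSE]
}

#' Remove blink-adjacent events
#'
#' Drops every event flagged as immediately preceding or following a blink
#' (`blink_before` or `blink_after`); all other events are preserved in
#' order. Blink adjacency is carried as flags in the input table rather
#' than re-derived from a blink event stream.
#'
#' @param events Event table.
#' @return Filtered event table.
#' @export
filter_blink_adjacent <- function(events) {
  drop <- (events$blink_before %in% TRUE) | (events$blink_after %in% TRUE)
  events[!drop, , drop = FALSE]
}

#' Remove search trials on which the target was found
#'
#' Search trials end early once the target is located, truncating the
#' eye-movement record, so they are excluded from classification. Trials
#' of other tasks are never removed, whatever their flags.
#'
#' @param events Event table.
#' @return Filtered event table.
#' @export
exclude_found_target_trials <- function(events) {
  drop <- events$task == "scene_search" & (events$target_found %in% TRUE)
  events[!drop, , drop = FALSE]
}

#' Apply the full preprocessing chain
#'
#' Runs the three exclusion rules ([filter_long_fixations()],
#' [filter_blink_adjacent()], [exclude_found_target_trials()]) and then
#' drops trials left with fewer than `min_fix` fixations or `min_sacc`
#' saccades, whose summary features would be undefined. The number of
#' trials dropped at this last step is reported via `message()` and
#' attached as attribute `n_dropped_trials`.
#'
#' @param events Event table.
#' @param max_fix_ms Long-fixation cutoff (default 1500 ms).
#' @param min_fix,min_sacc Minimum surviving events per trial (default 2).
#' @return Filtered event table.
#' @export
preprocess_events <- function(events, max_fix_ms = 1500, min_fix = 2,
                              min_sacc = 2) {
  ev <- filter_long_fixations(events, max_ms = max_fix_ms)
  ev <- filter_blink_adjacent(ev)
  ev <- exclude_found_target_trials(ev)
  key <- interaction(ev$participant, ev$session, ev$task, ev$trial,
                     drop = TRUE)
  n_fix <- tapply(ev$event_type == "fixation", key, sum)
  n_sacc <- tapply(ev$event_type == "saccade", key, sum)
  ok_keys <- names(n_fix)[n_fix >= min_fix & n_sacc >= min_sacc]
  dropped <- nlevels(key) - length(ok_keys)
  if (dropped > 0)
    message(sprintf("preprocess_events: dropped %d trial(s) with < %d %s",
                    dropped, min_fix, "fixations or saccades after filtering"))
  out <- ev[key %in% ok_keys, , drop = FALSE]
  attr(out, "n_dropped_trials") <- dropped
  out
}
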