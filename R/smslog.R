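# Append-only SMS event log with unsubscribe tracking.
#
# The SMS system records every incoming and outgoing message; program
# attrition (unsubscription) is derived from the incoming side of this log.

#' Create an empty SMS log
#'
#' @return Object of class `sms_log`: `events` tibble (`timestamp`,
#'   `direction`, `person_id`, `text`, `manual_unsubscribe`) and
#'   `unsubscribed_at`, a named list of POSIXct times.
#' @export
sms_log <- function() {
  structure(list(
    events = tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                    direction = character(), person_id = character(),
                    text = character(), manual_unsubscribe = logical()),
    unsubscribed_at = list()
  ), class = "sms_log")
}

#' Create an SMS event
#'
#' @param timestamp POSIXct event time.
#' @param direction `"in"` (from participant) or `"out"` (to participant).
#' @param person_id participant id.
#' @param text message text.
#' @param manual_unsubscribe set TRUE by an operator to force
#'   unsubscription for a free-text withdrawal request the keyword matcher
#'   would miss.
#' @return A named list.
#' @export
sms_event <- function(timestamp, direction, person_id, text,
                      manual_unsubscribe = FALSE) {
  assert_scalar_choice(direction, c("in", "out"), "direction")
  list(timestamp = as.POSIXct(timestamp, tz = "UTC"), direction = direction,
       person_id = as.character(person_id), text = as.character(text),
       manual_unsubscribe = isTRUE(manual_unsubscribe))
}

is_stop_message <- function(text, manual, config) {
  manual || tolower(trimws(text)) %in% config$stop_keywords
}

#' Apply an incoming event to the log
#'
#' Appends the event. If its text matches a configured stop keyword
#' (case-insensitive) or the event carries the manual-unsubscribe flag, the
#' sender's `unsubscribed_at` is set (idempotently: a second stop message
#' changes nothing). Events must arrive in time order per person.
#'
#' @param log an [sms_log()].
#' @param event an [sms_event()] with direction `"in"`.
#' @param config a [messaging_config()] (stop keywords).
#' @return The updated `sms_log`.
#' @export
apply_incoming <- function(log, event, config = messaging_config()) {
  if (event$direction != "in") abort_input("apply_incoming requires direction 'in'")
  prev <- log$events$timestamp[log$events$person_id == event$person_id]
  if (length(prev) > 0 && event$timestamp < max(prev))
    abort_input(sprintf("event for %s is older than the last logged event",
                        event$person_id))
  log$events <- bind_rows(log$events, as_tibble(event))
  if (is_stop_message(event$text, event$manual_unsubscribe, config) &&
      is.null(log$unsubscribed_at[[event$person_id]])) {
    log$unsubscribed_at[[event$person_id]] <- event$timestamp
  }
  log
}

#' Record an outgoing message
#'
#' Refuses to log a send to a person after their unsubscription time: after
#' a stop message no outgoing event can be emitted for that person.
#'
#' @inheritParams apply_incoming
#' @param event an [sms_event()] with direction `"out"`.
#' @return The updated `sms_log`.
#' @export
log_outgoing <- function(log, event) {
  if (event$direction != "out") abort_input("log_outgoing requires direction 'out'")
  ts <- log$unsubscribed_at[[event$person_id]]
  if (!is.null(ts) && event$timestamp >= ts)
    abort_input(sprintf("%s unsubscribed at %s; cannot send", event$person_id,
                        format(ts)))
  log$events <- bind_rows(log$events, as_tibble(event))
  log
}

#' Drop plan entries cancelled by an unsubscription
#'
#' @param plan a [plan_messages()] result.
#' @param log an [sms_log()].
#' @return The plan with entries at or after the person's unsubscription
#'   time removed.
#' @export
cancel_pending <- function(plan, log) {
  ts <- log$unsubscribed_at[[plan$person_id]]
  if (!is.null(ts)) plan$entries <- filter(plan$entries, send_datetime < ts)
  plan
}

#' Program attrition rate
#'
#' Share of program participants who unsubscribed (sent a stop message)
#' during the program.
#'
#' @param log an [sms_log()] (or a list of logs, pooled).
#' @param n_participants number of registered program participants (> 0).
#' @return Proportion in \[0, 1\].
#' @export
attrition_rate <- function(log, n_participants) {
  if (n_participants <= 0) abort_input("n_participants must be > 0")
  logs <- if (inherits(log, "sms_log")) list(log) else log
  n_unsub <- sum(vapply(logs, function(l) length(l$unsubscribed_at), 0L))
  n_unsub / n_participants
}

#' Read / write an SMS log as JSONL
#'
#' One JSON object per line (`timestamp`, `direction`, `person_id`, `text`,
#' `manual_unsubscribe`); reading replays incoming events through
#' [apply_incoming()] so the unsubscribe state is rebuilt.
#'
#' @param path JSONL file.
#' @param config a [messaging_config()].
#' @return An `sms_log` (`read_sms_log`); `path` invisibly
#'   (`write_sms_log`).
#' @export
read_sms_log <- function(path, config = messaging_config()) {
  lines <- readLines(path)
  log <- sms_log()
  for (line in lines[nzchar(lines)]) {
    x <- jsonlite::fromJSON(line)
    ev <- sms_event(as.POSIXct(x$timestamp, tz = "UTC"), x$direction,
                    x$person_id, x$text, isTRUE(x$manual_unsubscribe))
    log <- if (ev$direction == "in") apply_incoming(log, ev, config)
           else log_outgoing(log, ev)
  }
  log
}

#' @rdname read_sms_log
#' @param log an [sms_log()].
#' @export
write_sms_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log$events)), function(i) {
    row <- log$events[i, ]
    jsonlite::toJSON(list(timestamp = format(row$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
                          direction = row$direction, person_id = row$person_id,
                          text = row$text,
                          manual_unsubscribe = row$manual_unsubscribe),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
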