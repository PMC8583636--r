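# Smartwatch-side alert logic. Time is always injected (`now` arguments);
# the machine never reads a clock, so every behavior is deterministic and
# replayable. States: idle, fall_prompt (asking the user whether help is
# needed), sos_countdown (confirming a manual alert), alert_sent, cancelled.
# A fall prompt that receives no answer by its deadline always escalates to
# an automatic alert - the user may be unable to respond.

#' Create an alert state machine
#'
#' @param prompt_timeout seconds the fall prompt waits for a user response
#'   before escalating automatically. The deployed duration is unreported;
#'   30 s is a configurable default.
#' @param sos_hold seconds the display must be held to arm a manual SOS
#'   (3 s on the device).
#' @param sos_countdown seconds of cancellable countdown before a manual
#'   SOS alert is delivered (configurable default 5 s).
#' @return An `alert_machine` in state `"idle"` with an empty transition
#'   log.
#' @examples
#' m <- alert_machine()
#' m$state
#' @export
alert_machine <- function(prompt_timeout = 30, sos_hold = 3,
                          sos_countdown = 5) {
  stopifnot(prompt_timeout > 0, sos_hold > 0, sos_countdown > 0)
  structure(
    list(state = "idle", prompt_deadline = NA_real_,
         countdown_deadline = NA_real_, trigger = NA_character_,
         prompt_timeout = prompt_timeout, sos_hold = sos_hold,
         sos_countdown = sos_countdown,
         log = tibble::tibble(time = numeric(0), from = character(0),
                              to = character(0), action = character(0),
                              trigger = character(0))),
    class = "alert_machine"
  )
}

transition <- function(m, now, to, action, trigger = NA_character_) {
  m$log <- dplyr::bind_rows(m$log, tibble::tibble(
    time = now, from = m$state, to = to, action = action, trigger = trigger))
  m$state <- to
  if (to == "alert_sent") m$trigger <- trigger
  if (to %in% c("alert_sent", "cancelled", "idle")) {
    m$prompt_deadline <- NA_real_
    m$countdown_deadline <- NA_real_
  }
  m
}

#' Feed a fall event to the alert machine
#'
#' A confirmed fall event moves an idle machine to `fall_prompt`: the watch
#' asks the subject whether help is needed, with a deadline of
#' `now + prompt_timeout`. Non-fall events are a no-op.
#'
#' @param m an [alert_machine()].
#' @param event a one-row `fall_events` tibble (see [classify_fall()]) or
#'   any list with an `is_fall` flag.
#' @param now current time, seconds.
#' @return the updated machine.
#' @export
on_fall_event <- function(m, event, now) {
  stopifnot(inherits(m, "alert_machine"))
  is_fall <- if (is.data.frame(event)) any(event$is_fall) else isTRUE(event$is_fall)
  if (!is_fall || m$state != "idle") return(m)
  m <- transition(m, now, "fall_prompt", "fall_event")
  m$prompt_deadline <- now + m$prompt_timeout
  m
}

#' Respond to the fall prompt
#'
#' A response received before the prompt deadline resolves the prompt:
#' `"help_needed"` sends the alert (trigger `fall_confirmed`),
#' `"ok"` cancels it. Responses at or after the deadline, or in any other
#' state, are no-ops (the deadline escalation wins).
#'
#' @param m an [alert_machine()] in state `fall_prompt`.
#' @param response `"help_needed"` or `"ok"`.
#' @param now current time, seconds.
#' @return the updated machine.
#' @export
user_response <- function(m, response = c("help_needed", "ok"), now) {
  stopifnot(inherits(m, "alert_machine"))
  response <- match.arg(response)
  if (m$state != "fall_prompt" || now >= m$prompt_deadline) return(m)
  if (response == "help_needed") {
    transition(m, now, "alert_sent", "user_response", "fall_confirmed")
  } else {
    transition(m, now, "cancelled", "user_response")
  }
}

#' Press-and-hold SOS
#'
#' The user presses and holds the display; holding for the SOS hold time
#' (3 s) arms a cancellable countdown, after which the alert is delivered
#' with trigger `sos`. A shorter hold is a no-op.
#'
#' @param m an [alert_machine()] in state `idle`.
#' @param press_start time the press began, seconds.
#' @param release time the press ended, or `NULL` if still held.
#' @return the updated machine.
#' @export
on_sos_press <- function(m, press_start, release = NULL) {
  stopifnot(inherits(m, "alert_machine"))
  if (m$state != "idle") return(m)
  hold <- if (is.null(release)) Inf else release - press_start
  if (hold < m$sos_hold) return(m)
  armed_at <- press_start + m$sos_hold
  m <- transition(m, armed_at, "sos_countdown", "sos_hold")
  m$countdown_deadline <- armed_at + m$sos_countdown
  m
}

#' Cancel a pending SOS countdown
#'
#' @param m an [alert_machine()] in state `sos_countdown`.
#' @param now current time, seconds; must precede the countdown deadline.
#' @return the updated machine.
#' @export
cancel_alert <- function(m, now) {
  stopifnot(inherits(m, "alert_machine"))
  if (m$state != "sos_countdown" || now >= m$countdown_deadline) return(m)
  transition(m, now, "cancelled", "cancel")
}

#' Advance the machine clock
#'
#' Fires any deadline that `t` has reached: an unanswered fall prompt
#' escalates to `alert_sent` with trigger `fall_auto`; an uncancelled SOS
#' countdown delivers the alert with trigger `sos`.
#'
#' @param m an [alert_machine()].
#' @param t current time, seconds.
#' @return the updated machine.
#' @export
tick <- function(m, t) {
  stopifnot(inherits(m, "alert_machine"))
  if (m$state == "fall_prompt" && t >= m$prompt_deadline) {
    return(transition(m, t, "alert_sent", "tick", "fall_auto"))
  }
  if (m$state == "sos_countdown" && t >= m$countdown_deadline) {
    return(transition(m, t, "alert_sent", "tick", "sos"))
  }
  m
}

#' @export
print.alert_machine <- function(x, ...) {
  cat(sprintf("<alert_machine> state: %s", x$state))
  if (!is.na(x$prompt_deadline)) {
    cat(sprintf(" (prompt deadline %g s)", x$prompt_deadline))
  }
  if (!is.na(x$countdown_deadline)) {
    cat(sprintf(" (countdown deadline %g s)", x$countdown_deadline))
  }
  if (x$state == "alert_sent") cat(sprintf(" [trigger: %s]", x$trigger))
  cat(sprintf("\n  %d transition(s) logged\n", nrow(x$log)))
  invisible(x)
}

# ---- event log --------------------------------------------------------------

#' Append-only gateway event log
#'
#' Typed, chronological record store for everything the gateway surfaces:
#' falls, alerts, activity reports, breathing summaries, reminders and
#' heart-rate passthrough records. Appends must be in chronological order;
#' queries retrieve a closed time range in order.
#'
#' @return `event_log()`: an empty `event_log` tibble (`time`, `type`,
#'   `payload` list-column).
#' @examples
#' log <- event_log()
#' log <- log_append(log, 10, "fall", list(impact_time = 9.5))
#' log_query(log, 0, 100)
#' @export
event_log <- function() {
  structure(tibble::tibble(time = numeric(0), type = character(0),
                           payload = list()),
            class = c("event_log", class(tibble::tibble())))
}

#' @param log an `event_log`.
#' @param time event time (seconds or epoch); must not precede the last
#'   appended event.
#' @param type record type string (e.g. `"fall"`, `"alert"`,
#'   `"activity_report"`, `"breathing_summary"`, `"reminder"`,
#'   `"heart_rate"`).
#' @param payload arbitrary record content (list).
#' @rdname event_log
#' @export
log_append <- function(log, time, type, payload = list()) {
  stopifnot(inherits(log, "event_log"))
  if (nrow(log) > 0 && time < max(log$time)) {
    stop("log_append: out-of-order append (log is append-only, ", time,
         " precedes ", max(log$time), ")", call. = FALSE)
  }
  out <- dplyr::bind_rows(log, tibble::tibble(time = time, type = type,
                                              payload = list(payload)))
  class(out) <- class(log)
  out
}

#' @param from,to closed query range; `from` must not exceed `to`.
#' @rdname event_log
#' @export
log_query <- function(log, from, to) {
  stopifnot(inherits(log, "event_log"))
  if (from > to) {
    stop("log_query: invalid range (start ", from, " > end ", to, ")",
         call. = FALSE)
  }
  out <- log[log$time >= from & log$time <= to, , drop = FALSE]
  out[order(out$time), , drop = FALSE]
}

#' Write an event log as JSONL
#'
#' One typed record per line, timestamps rendered as ISO-8601 when given a
#' reference origin.
#'
#' @param log an `event_log`.
#' @param path output file.
#' @param origin POSIXct origin for the numeric times (default the Unix
#'   epoch, UTC).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path,
                            origin = as.POSIXct("1970-01-01", tz = "UTC")) {
  stopifnot(inherits(log, "event_log"))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- list(
      timestamp = format(origin + log$time[i], "%Y-%m-%dT%H:%M:%OS3Z",
                         tz = "UTC"),
      type = log$type[i],
      payload = log$payload[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
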