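fall_event_stub <- function(is_fall = TRUE) list(is_fall = is_fall)

test_that("an unanswered fall prompt always escalates automatically", {
  m <- alert_machine()
  m <- on_fall_event(m, fall_event_stub(), now = 100)
  expect_identical(m$state, "fall_prompt")
  expect_identical(m$prompt_deadline, 130)
  m <- tick(m, 129.9)
  expect_identical(m$state, "fall_prompt")
  m <- tick(m, 130)
  expect_identical(m$state, "alert_sent")
  expect_identical(m$trigger, "fall_auto")
})

test_that("user responses before the deadline resolve the prompt", {
  m0 <- on_fall_event(alert_machine(), fall_event_stub(), now = 0)
  ok <- user_response(m0, "ok", now = 29)
  expect_identical(ok$state, "cancelled")
  help <- user_response(m0, "help_needed", now = 5)
  expect_identical(help$state, "alert_sent")
  expect_identical(help$trigger, "fall_confirmed")
  # at/after the deadline the response is too late
  late <- user_response(m0, "ok", now = 30)
  expect_identical(late$state, "fall_prompt")
})

test_that("non-fall events are a no-op", {
  m <- on_fall_event(alert_machine(), fall_event_stub(FALSE), now = 0)
  expect_identical(m$state, "idle")
  expect_identical(nrow(m$log), 0L)
})

test_that("SOS requires a 3 s hold and a completed countdown", {
  m <- on_sos_press(alert_machine(), press_start = 10, release = 13.0)
  expect_identical(m$state, "sos_countdown")
  expect_identical(m$countdown_deadline, 18)   # armed at 13, 5 s countdown
  sent <- tick(m, 18)
  expect_identical(sent$state, "alert_sent")
  expect_identical(sent$trigger, "sos")
  short <- on_sos_press(alert_machine(), press_start = 10, release = 12.9)
  expect_identical(short$state, "idle")
  held <- on_sos_press(alert_machine(), press_start = 10, release = NULL)
  expect_identical(held$state, "sos_countdown")
  cancelled <- cancel_alert(on_sos_press(alert_machine(), 10, 14), now = 16)
  expect_identical(cancelled$state, "cancelled")
})

test_that("alerts are unreachable without a legitimate trigger (exhaustive)", {
  # deterministic actions; `now` advances so deadlines can be crossed
  actions <- list(
    fall_true = function(m, now) on_fall_event(m, fall_event_stub(TRUE), now),
    fall_false = function(m, now) on_fall_event(m, fall_event_stub(FALSE), now),
    respond_ok = function(m, now) user_response(m, "ok", now),
    respond_help = function(m, now) user_response(m, "help_needed", now),
    sos_long = function(m, now) on_sos_press(m, now, now + 3),
    sos_short = function(m, now) on_sos_press(m, now, now + 2.9),
    cancel = function(m, now) cancel_alert(m, now),
    tick_small = function(m, now) tick(m, now),
    tick_past = function(m, now) {
      d <- suppressWarnings(max(m$prompt_deadline, m$countdown_deadline,
                                na.rm = TRUE))
      tick(m, if (is.finite(d)) max(now, d) else now)
    }
  )
  signature <- function(m) m$state
  seen <- character(0)
  frontier <- list(list(m = alert_machine(), now = 0))
  edges <- 0L
  while (length(frontier) > 0) {
    nxt <- list()
    for (node in frontier) {
      sig <- signature(node$m)
      if (sig %in% seen) next
      seen <- c(seen, sig)
      for (nm in names(actions)) {
        m2 <- actions[[nm]](node$m, node$now)
        edges <- edges + 1L
        if (m2$state == "alert_sent" && node$m$state != "alert_sent") {
          # safety: only a fall prompt or an armed SOS countdown may send
          expect_true(node$m$state %in% c("fall_prompt", "sos_countdown"))
          expect_true(m2$trigger %in% c("fall_auto", "fall_confirmed", "sos"))
        }
        if (m2$state == "cancelled" && node$m$state != "cancelled") {
          expect_true(node$m$state %in% c("fall_prompt", "sos_countdown"))
        }
        nxt <- c(nxt, list(list(m = m2, now = node$now + 1)))
      }
    }
    frontier <- nxt
  }
  expect_setequal(seen, c("idle", "fall_prompt", "sos_countdown",
                          "alert_sent", "cancelled"))
  expect_gte(edges, length(seen) * length(actions) - length(actions))
})

test_that("from fall_prompt every timeline resolves by the deadline (liveness)", {
  m0 <- on_fall_event(alert_machine(), fall_event_stub(), now = 0)
  resolutions <- list(
    function(m) tick(m, m$prompt_deadline),
    function(m) user_response(m, "ok", 1),
    function(m) user_response(m, "help_needed", 1),
    function(m) tick(user_response(on_sos_press(m, 1, 5), "ok", 29.5),
                     m$prompt_deadline)
  )
  for (r in resolutions) {
    out <- r(m0)
    expect_true(out$state %in% c("alert_sent", "cancelled"))
  }
  # no sequence of non-resolving actions survives a tick at the deadline
  m <- m0
  m <- on_fall_event(m, fall_event_stub(), 5)    # ignored: not idle
  m <- on_sos_press(m, 6, 10)                    # ignored: not idle
  m <- cancel_alert(m, 7)                        # ignored: no countdown
  expect_identical(m$state, "fall_prompt")
  expect_identical(tick(m, m$prompt_deadline)$state, "alert_sent")
})

test_that("every sent alert records its trigger in the transition log", {
  m <- tick(on_fall_event(alert_machine(), fall_event_stub(), 0), 30)
  sent <- m$log[m$log$to == "alert_sent", ]
  expect_identical(nrow(sent), 1L)
  expect_identical(sent$trigger, "fall_auto")
})

test_that("the event log is append-only and queries chronologically", {
  log <- event_log()
  log <- log_append(log, 10, "fall", list(impact_time = 9.5))
  log <- log_append(log, 20, "alert", list(trigger = "fall_auto"))
  log <- log_append(log, 30, "activity_report", list(reps = 6))
  got <- log_query(log, 0, 100)
  expect_identical(nrow(got), 3L)
  expect_identical(got$type, c("fall", "alert", "activity_report"))
  expect_identical(nrow(log_query(log, 11, 19)), 0L)
  expect_error(log_append(log, 5, "fall"), "append-only")
  expect_error(log_query(log, 50, 10), "invalid range")
})

test_that("event logs serialize as one ISO-8601 JSONL record per line", {
  log <- log_append(event_log(), 60, "breathing_summary", list(rate = 12))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, f)
  lines <- readLines(f)
  expect_length(lines, 1)
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$type, "breathing_summary")
  expect_identical(rec$payload$rate, 12L)
  expect_match(rec$timestamp, "^1970-01-01T00:01:00")
})
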