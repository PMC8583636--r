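# Stage-2, gateway-side fall decision. Each impact excerpt is classified
# from three features named by the personalization table: posture transition
# (gravity projection on the trunk axis before and after the impact), impact
# energy, and net vertical displacement. A fall is the conjunction of all
# criteria; this is what separates genuine falls from abrupt sit-downs or
# lying down, which share some but never all of the features.

POSTURE_SEGMENT_S <- 1      # posture is read on 1 s pre/post segments
DISP_PRE_S <- 0.85          # active integration interval around the impact
DISP_POST_S <- 0.35         # (descent + spike live within ~0.75 s of the peak)
DISP_REFINE_S <- 0.5        # impact re-centering search radius

#' Classify trunk posture from an acceleration segment
#'
#' Computes the mean gravity projection on the trunk-longitudinal axis
#' (device x) over the segment. At or above the vertical threshold
#' (6.5 m/s^2 by default) the posture is `"vertical"`; at or below the
#' horizontal threshold (2.5 m/s^2) it is `"horizontal"`. Between the two
#' thresholds the nearer class wins; the exact midpoint resolves to
#' `"vertical"`, the non-alarm direction.
#'
#' @param segment acceleration samples (`t, ax, ay, az`), at least 0.5 s.
#' @param config a [detector_config()].
#' @return `"vertical"` or `"horizontal"`.
#' @examples
#' standing <- tibble::tibble(t = (0:39) / 40, ax = 9.81, ay = 0, az = 0)
#' classify_posture(standing)
#' @export
classify_posture <- function(segment, config = detector_config()) {
  segment <- as_accel_stream(segment)
  if (nrow(segment) < 0.5 * config$fs) {
    stop("classify_posture: segment must span at least 0.5 s", call. = FALSE)
  }
  proj <- mean(segment$ax)
  v <- config$vertical_posture_threshold
  h <- config$horizontal_posture_threshold
  if (proj >= v) return("vertical")
  if (proj <= h) return("horizontal")
  if (abs(proj - v) <= abs(proj - h)) "vertical" else "horizontal"
}

#' Net vertical displacement across an impact window
#'
#' Estimates the sensor's net vertical displacement (m, downward negative)
#' around the impact by doubly integrating the gravity-compensated vertical
#' acceleration, taken as the deviation of the acceleration magnitude from
#' static gravity (during partial free fall the magnitude drops below g;
#' the impact deceleration restores it). Two drift controls are applied:
#' a baseline fitted linearly to the quiet flanks of the window and
#' interpolated across the active interval (1.2 s before to 0.6 s after the
#' impact), and a zero-velocity anchor on each flank (the sensor is quiet
#' before the descent and after the impact, so the flank-mean velocities
#' are pinned to zero by a linear ramp) before the second integration. The
#' displacement is the trapezoidal integral of the corrected velocity over
#' the active interval, where the event's momentum exchange lives; for a
#' bounded periodic acceleration the same construction leaves only the
#' bounded oscillatory term.
#'
#' @param window one row of [detect_impacts()] output (or equivalent list).
#' @return Net signed displacement in meters; `NA` for truncated windows
#'   (insufficient context to anchor the baseline).
#' @examples
#' w <- detect_impacts(gen_fall("fall_from_bed", 10, 0, 4)$stream)[1, ]
#' vertical_displacement(w) < -0.12
#' @export
vertical_displacement <- function(window) {
  w <- normalize_window(window)
  if (isTRUE(w$truncated)) return(NA_real_)
  s <- as_accel_stream(w$window)
  t <- s$t
  av <- stream_magnitude(s) - FW_G
  # re-center on the deceleration peak: the stage-1 energy maximum can sit
  # mid-descent, and a tight, well-centered interval integrates less noise
  near <- which(abs(t - w$impact_time) <= DISP_REFINE_S)
  tc <- t[near[which.max(abs(av[near]))]]
  act <- t >= tc - DISP_PRE_S & t <= tc + DISP_POST_S
  pre_flank <- t < tc - DISP_PRE_S
  post_flank <- t > tc + DISP_POST_S
  if (sum(act) < 3) return(0)
  if (any(pre_flank) && any(post_flank)) {
    av <- av - flank_secant(t, av, pre_flank, post_flank)
  }
  dt <- diff(t)
  v <- cumsum(c(0, dt * (utils::head(av, -1) + utils::tail(av, -1)) / 2))
  if (any(pre_flank) && any(post_flank)) {
    v <- v - flank_secant(t, v, pre_flank, post_flank)
  } else {
    v <- v - seq(v[1], v[length(v)], length.out = length(v))
  }
  ta <- t[act]
  va <- v[act]
  sum(diff(ta) * (utils::head(va, -1) + utils::tail(va, -1)) / 2)
}

# Secant through the smoothed signal at the two flank centers. Smoothing
# (0.8 s moving average) rejects oscillatory leakage into the anchors, so a
# zero-mean periodic signal contributes only its bounded integral; the
# secant tracks slow drift across the active gap.
flank_secant <- function(t, x, pre, post) {
  sm <- as.numeric(stats::filter(x, rep(1 / 33, 33), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  x_pre <- mean(sm[pre]); t_pre <- mean(t[pre])
  x_post <- mean(sm[post]); t_post <- mean(t[post])
  x_pre + (x_post - x_pre) * (t - t_pre) / (t_post - t_pre)
}

#' Classify an impact window as fall or non-fall (stage 2)
#'
#' Applies the decision rule to one impact excerpt: the event is a fall when
#' the impact energy reaches the fall energy threshold AND the pre-impact
#' posture (first second of the excerpt) is vertical AND the post-impact
#' posture (last second) is horizontal AND the net vertical displacement is
#' at or below the descending threshold. For truncated excerpts the decision
#' uses whichever criteria are computable and the event is flagged
#' low-confidence.
#'
#' @param window one row of [detect_impacts()] output.
#' @param config a [detector_config()].
#' @return A one-row tibble (`fall_event`): `impact_time`, `is_fall`,
#'   `impact_energy`, `pre_posture`, `post_posture`,
#'   `vertical_displacement`, `truncated`, `low_confidence`, plus the
#'   `config` snapshot as an attribute.
#' @examples
#' w <- detect_impacts(gen_fall("fall_knees", 10, 0, 3)$stream)[1, ]
#' classify_fall(w)$is_fall
#' @export
classify_fall <- function(window, config = detector_config()) {
  w <- normalize_window(window)
  s <- as_accel_stream(w$window)
  fs <- config$fs
  npost <- min(nrow(s), round(POSTURE_SEGMENT_S * fs))
  pre <- s[seq_len(min(nrow(s), round(POSTURE_SEGMENT_S * fs))), ]
  post <- s[(nrow(s) - npost + 1):nrow(s), ]
  pre_posture <- classify_posture(pre, config)
  post_posture <- classify_posture(post, config)
  vdisp <- vertical_displacement(w)
  energy_ok <- w$peak_energy >= config$fall_energy_threshold
  posture_ok <- pre_posture == "vertical" && post_posture == "horizontal"
  disp_ok <- if (is.na(vdisp)) TRUE else
    vdisp <= config$descending_displacement_threshold
  is_fall <- energy_ok && posture_ok && disp_ok
  out <- tibble::tibble(
    impact_time = w$impact_time,
    is_fall = is_fall,
    impact_energy = w$peak_energy,
    pre_posture = pre_posture,
    post_posture = post_posture,
    vertical_displacement = vdisp,
    truncated = isTRUE(w$truncated),
    low_confidence = isTRUE(w$truncated)
  )
  attr(out, "config") <- config
  class(out) <- c("fall_events", class(out))
  out
}

#' Run both detection stages on a stream
#'
#' Convenience pipeline: stage-1 impact detection followed by stage-2
#' classification of every emitted window.
#'
#' @param stream an acceleration stream (`t, ax, ay, az`).
#' @param config a [detector_config()].
#' @return A `fall_events` tibble with one row per impact window (possibly
#'   zero rows).
#' @examples
#' detect_falls(gen_fall("fall_from_chair", 10, 0, 7)$stream)$is_fall
#' @export
detect_falls <- function(stream, config = detector_config()) {
  impacts <- detect_impacts(stream, config)
  if (nrow(impacts) == 0) {
    out <- tibble::tibble(impact_time = numeric(0), is_fall = logical(0),
                          impact_energy = numeric(0),
                          pre_posture = character(0),
                          post_posture = character(0),
                          vertical_displacement = numeric(0),
                          truncated = logical(0), low_confidence = logical(0))
    attr(out, "config") <- config
    class(out) <- c("fall_events", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(
    purrr::map(seq_len(nrow(impacts)),
               function(i) classify_fall(impacts[i, ], config))
  )
  attr(out, "config") <- config
  class(out) <- c("fall_events", class(out))
  out
}

#' Evaluate the detector over a labeled protocol
#'
#' Runs both detection stages over every stream of a generated protocol and
#' scores the result against ground truth: sensitivity is the percentage of
#' true falls matched by a fall alarm within +/- 2 s; specificity is the
#' percentage of fall-free activity instances that produced no fall alarm.
#'
#' @param streams the tibble returned by [gen_protocol_sequence()], or a
#'   plain list of `labeled_stream` objects.
#' @param config a [detector_config()].
#' @param match_window_s tolerance for matching an alarm to a true fall.
#' @param detector the detector to score: a function of
#'   `(stream, config)` returning a `fall_events` tibble. Defaults to the
#'   package's two-stage pipeline [detect_falls()]; substitutable so that
#'   degenerate or external detectors can be scored with the same rules.
#' @return A `protocol_eval` object: list with `sensitivity`, `specificity`
#'   (percent), counts, and a `per_stream` tibble. Use [generics::glance()]
#'   or [generics::tidy()] for tabular access.
#' @examples
#' prot <- gen_protocol_sequence(1, 1, noise_sd = 0, seed = 10)
#' evaluate_protocol(prot)
#' @export
evaluate_protocol <- function(streams, config = detector_config(),
                              match_window_s = 2, detector = detect_falls) {
  if (is.data.frame(streams) && "stream" %in% names(streams)) {
    lst <- streams$stream
    meta <- streams[, intersect(c("subject", "repetition", "activity"),
                                names(streams))]
  } else if (is.list(streams)) {
    if (inherits(streams, "labeled_stream")) streams <- list(streams)
    lst <- streams
    meta <- NULL
  } else {
    stop("evaluate_protocol: expected a protocol tibble or a list of ",
         "labeled streams", call. = FALSE)
  }
  if (!all(vapply(lst, inherits, TRUE, "labeled_stream"))) {
    stop("evaluate_protocol: streams must be labeled", call. = FALSE)
  }
  has_truth <- vapply(lst, function(x) !is.null(x$truth$falls), TRUE)
  if (!all(has_truth)) {
    stop("evaluate_protocol: ground-truth annotations are required",
         call. = FALSE)
  }
  per <- purrr::map_dfr(seq_along(lst), function(i) {
    ls <- lst[[i]]
    ev <- detector(ls$stream, config)
    alarms <- ev$impact_time[ev$is_fall]
    true_falls <- ls$truth$falls
    matched <- vapply(true_falls, function(tf) {
      any(abs(alarms - tf) <= match_window_s)
    }, TRUE)
    false_alarms <- vapply(alarms, function(a) {
      length(true_falls) == 0 || all(abs(a - true_falls) > match_window_s)
    }, TRUE)
    tibble::tibble(idx = i, kind = ls$kind,
                   is_fall_stream = length(true_falls) > 0,
                   n_true = length(true_falls),
                   n_matched = sum(matched),
                   n_alarms = length(alarms),
                   n_false_alarms = sum(false_alarms))
  })
  if (!is.null(meta) && nrow(meta) == nrow(per)) per <- dplyr::bind_cols(meta, per)
  n_falls <- sum(per$n_true)
  n_fall_free <- sum(!per$is_fall_stream)
  sens <- if (n_falls > 0) 100 * sum(per$n_matched) / n_falls else NA_real_
  spec <- if (n_fall_free > 0) {
    100 * sum(!per$is_fall_stream & per$n_false_alarms == 0) / n_fall_free
  } else NA_real_
  structure(
    list(sensitivity = sens, specificity = spec, n_falls = n_falls,
         n_fall_free = n_fall_free, per_stream = per, config = config),
    class = "protocol_eval"
  )
}

#' @export
print.protocol_eval <- function(x, ...) {
  cat("<protocol_eval>\n")
  cat(sprintf("  true falls:          %d\n", x$n_falls))
  cat(sprintf("  fall-free instances: %d\n", x$n_fall_free))
  cat(sprintf("  sensitivity:         %.1f %%\n", x$sensitivity))
  cat(sprintf("  specificity:         %.1f %%\n", x$specificity))
  invisible(x)
}
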