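# Respiratory waveform processing from the vest's capacitive channel. The
# expansion signal is a sawtooth-like waveform (rising flank = inspiration,
# falling flank = expiration); the same hysteresis cycle engine used for
# exercise accelerometry segments it, with two respiratory specifics: no
# band-pass (controlled breathing can be as slow as 4 breaths/min) and an
# amplitude floor relative to the signal's own excursion range, which makes
# the segmentation invariant under positive rescaling of the arbitrary
# capacitance units.

RESP_MIN_PERIOD_S <- 1     # 60 breaths/min physiological ceiling
RESP_REL_FLOOR <- 0.2      # hysteresis floor: 20% of the 5-95% range

#' Segment a respiratory signal into breath cycles
#'
#' Reuses the sawtooth parameterization on the respiratory channel: each
#' cycle runs trough (inspiration start) - peak (inspiration end =
#' expiration start) - trough (expiration end). Cycles shorter than 1 s
#' (above the 60 breaths/min ceiling) are rejected as noise micro-cycles.
#' When a concurrent acceleration stream is supplied, any cycle overlapping
#' an interval where the magnitude deviates from static gravity by more
#' than the intense-motion artifact threshold is flagged `artifact_gated`;
#' gated cycles never contribute to rate estimates.
#'
#' @param resp a respiratory stream (`t, amplitude`), at least 10 s.
#' @param accel optional concurrent acceleration stream (`t, ax, ay, az`).
#' @param config a [detector_config()].
#' @return A `breath_cycles` tibble: `insp_start`, `insp_end`, `exp_end`,
#'   `t_insp`, `t_exp`, `artifact_gated`.
#' @examples
#' r <- gen_breathing(data.frame(rate = 6, n_cycles = 3), noise_sd = 0)
#' segment_breaths(r$stream)
#' @export
segment_breaths <- function(resp, accel = NULL, config = detector_config()) {
  resp <- as_resp_stream(resp)
  if (max(resp$t) - min(resp$t) < 10) {
    stop("segment_breaths: insufficient data (need at least 10 s)",
         call. = FALSE)
  }
  x <- resp$amplitude - stats::median(resp$amplitude)
  qr <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  floor_amp <- RESP_REL_FLOOR * (qr[2] - qr[1])
  cycles <- tibble::tibble(insp_start = numeric(0), insp_end = numeric(0),
                           exp_end = numeric(0), t_insp = numeric(0),
                           t_exp = numeric(0), flank_ref = numeric(0),
                           artifact_gated = logical(0))
  if (floor_amp > 0) {
    ext <- hysteresis_extrema(x, floor_amp)
    cy <- extrema_to_cycles(x, resp$t, ext, "amplitude")
    cy <- cy[cy$period >= RESP_MIN_PERIOD_S, , drop = FALSE]
    if (nrow(cy) > 0) {
      cycles <- tibble::tibble(
        insp_start = cy$start_time, insp_end = cy$peak_time,
        exp_end = cy$end_time, t_insp = cy$rise_duration,
        t_exp = cy$fall_duration,
        flank_ref = flank_crossing(resp$t, x, cy),
        artifact_gated = FALSE
      )
    }
  }
  if (!is.null(accel) && nrow(cycles) > 0) {
    accel <- as_accel_stream(accel)
    dev <- abs(stream_magnitude(accel) - FW_G)
    intense <- motion_intervals(accel$t, dev,
                                config$intense_motion_artifact_threshold)
    if (nrow(intense) > 0) {
      cycles$artifact_gated <- vapply(seq_len(nrow(cycles)), function(i) {
        any(cycles$insp_start[i] < intense$end &
              cycles$exp_end[i] > intense$start)
      }, TRUE)
    }
  }
  class(cycles) <- c("breath_cycles", class(cycles))
  cycles
}

# Timing reference of each cycle: the instant the inspiratory flank
# crosses the half-amplitude level, linearly interpolated between samples.
# The flank is the steepest part of the cycle, so this reference jitters
# far less under slow baseline wander than the flat troughs and peaks do;
# cycle-to-cycle differences of the reference give the most stable period
# estimate.
flank_crossing <- function(t, x, cy) {
  vapply(seq_len(nrow(cy)), function(i) {
    i0 <- which.min(abs(t - cy$start_time[i]))
    i1 <- which.min(abs(t - cy$peak_time[i]))
    if (i1 <= i0) return((cy$start_time[i] + cy$peak_time[i]) / 2)
    level <- (x[i0] + x[i1]) / 2
    seg <- x[i0:i1]
    k <- which(seg[-1] >= level & seg[-length(seg)] < level)
    if (length(k) == 0) return((cy$start_time[i] + cy$peak_time[i]) / 2)
    k <- k[1]
    frac <- (level - seg[k]) / (seg[k + 1] - seg[k])
    t[i0 + k - 1] + frac * (t[2] - t[1])
  }, numeric(1))
}

# contiguous runs where the deviation exceeds the threshold
motion_intervals <- function(t, dev, threshold) {
  above <- dev > threshold
  if (!any(above)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = t[starts[keep]], end = t[ends[keep]])
}

#' Respiratory rate series
#'
#' Sliding-window respiratory rate from segmented breath cycles: at each
#' non-gated cycle's end, the rate is 60 divided by the mean duration of
#' the non-gated cycles that ended within the trailing window. Gated cycles
#' never contribute.
#'
#' @param cycles a `breath_cycles` tibble from [segment_breaths()].
#' @param window trailing window length in seconds.
#' @return A tibble: `t` (cycle end time), `rate` (breaths/min).
#' @examples
#' r <- gen_breathing(data.frame(rate = 12, n_cycles = 4), noise_sd = 0)
#' respiratory_rate(segment_breaths(r$stream))
#' @export
respiratory_rate <- function(cycles, window = 30) {
  ok <- cycles[!cycles$artifact_gated, , drop = FALSE]
  if (nrow(ok) == 0) {
    stop("respiratory_rate: no valid (non-gated) breath cycles",
         call. = FALSE)
  }
  dur <- ok$t_insp + ok$t_exp
  purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    sel <- ok$exp_end > ok$exp_end[i] - window & ok$exp_end <= ok$exp_end[i]
    tibble::tibble(t = ok$exp_end[i], rate = 60 / mean(dur[sel]))
  })
}

#' Evaluate a controlled-breathing protocol
#'
#' Scores the segmentation against the programmed protocol of a generated
#' breathing stream: for each programmed rate segment, the estimated rate
#' (60 / mean duration of the cycles starting in the segment), the absolute
#' rate error, and the mean absolute timing errors of the inspiration and
#' expiration boundaries against ground truth.
#'
#' @param ls a `labeled_stream` from [gen_breathing()].
#' @param accel optional concurrent acceleration stream for artifact gating.
#' @param config a [detector_config()].
#' @return A tibble with one row per protocol segment: `rate`,
#'   `estimated_rate`, `rate_error`, `n_cycles_true`, `n_cycles_found`,
#'   `insp_time_mae`, `exp_time_mae`.
#' @examples
#' ls <- gen_breathing(breathing_ramp_pattern(), noise_sd = 0)
#' evaluate_breathing_protocol(ls)
#' @export
evaluate_breathing_protocol <- function(ls, accel = NULL,
                                        config = detector_config()) {
  if (!inherits(ls, "labeled_stream") || ls$channel != "resp" ||
      is.null(ls$truth$segments)) {
    stop("evaluate_breathing_protocol: expected a generated breathing ",
         "stream with protocol ground truth", call. = FALSE)
  }
  cycles <- segment_breaths(ls$stream, accel, config)
  ok <- cycles[!cycles$artifact_gated, , drop = FALSE]
  truth <- ls$truth
  # cycles are attributed to protocol segments by their midpoint: boundary
  # troughs jitter under noise, and a cycle whose start slips marginally
  # across a rate change must not pollute the neighbouring segment
  mid <- (ok$insp_start + ok$exp_end) / 2
  purrr::map_dfr(seq_len(nrow(truth$segments)), function(k) {
    seg <- truth$segments[k, ]
    est <- ok[mid >= seg$start - 1e-9 & mid < seg$end - 1e-9, , drop = FALSE]
    tb <- truth$breaths[truth$breaths$insp_start >= seg$start - 1e-9 &
                          truth$breaths$insp_start < seg$end - 1e-9, ,
                        drop = FALSE]
    # segment rate from flank-reference spacings when two or more cycles
    # are available (stable under baseline wander), else from durations
    est_rate <- if (nrow(est) >= 2) {
      60 / mean(diff(est$flank_ref))
    } else if (nrow(est) == 1) {
      60 / (est$t_insp + est$t_exp)
    } else NA_real_
    tim <- function(est_t, true_t) {
      if (nrow(est) == 0) return(NA_real_)
      mean(vapply(true_t, function(tt) min(abs(est_t - tt)), numeric(1)))
    }
    tibble::tibble(
      rate = seg$rate,
      estimated_rate = est_rate,
      rate_error = abs(est_rate - seg$rate),
      n_cycles_true = nrow(tb),
      n_cycles_found = nrow(est),
      insp_time_mae = tim(est$insp_start, tb$insp_start),
      exp_time_mae = tim(est$exp_end, tb$exp_end)
    )
  })
}
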