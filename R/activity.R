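# Sawtooth parameterization of exercise accelerometry. Both maintenance
# exercises and respiration produce quasi-triangular ("sawtooth-like")
# waveforms; the vest abstracts them into per-cycle features (extrema times,
# amplitude, rise/fall durations) from which repetitions, activity class and
# metabolic expenditure are derived.

SAW_SELECT_BAND_HZ <- c(0.2, 3)   # cadence band for dominant-axis selection
# The segmentation filter reaches further down (0.08 Hz) so that the
# slowest maintenance exercises (4-5 s cycles, i.e. 0.2-0.25 Hz
# fundamentals) pass without attenuation; a high-pass at 0.2 Hz would sit
# on top of their fundamental and clip cycle amplitudes near the
# hysteresis floor.
SAW_BAND_HZ <- c(0.08, 3)
MET_EPOCH_S <- 10            # actigraphy epoch for metabolic expenditure
MET_WALK_ANCHOR <- 0.64      # mean rectified band-passed |a| of walking, m/s^2
MET_WALK_VALUE <- 3.5        # MET assigned to the walking anchor
REST_ENERGY_WINDOW <- 41L    # 1 s energy window for rest masking

# hysteresis amplitude floor implied by the movement activity energy
# threshold: peak-to-trough amplitude of a sinusoid whose variance equals
# the threshold, doubled for margin against sub-movement wiggles
hysteresis_floor <- function(config) {
  2 * sqrt(2 * config$movement_activity_energy_threshold)
}

# Zero-phase band-pass. The high-pass leg subtracts a centered moving
# average (half-power near the requested cutoff): at the very low cutoffs
# this module needs (0.08-0.2 Hz at 40 Hz sampling, i.e. normalized
# frequencies of a few 1e-3) an IIR high-pass is numerically fragile,
# while moving-average subtraction is exact, stable and phase-free. The
# low-pass leg is a 2nd-order Butterworth run forward-backward. The signal
# is extended by odd reflection at both ends so neither leg rings at the
# stream boundaries.
bandpass <- function(x, fs, band) {
  n <- length(x)
  pad <- min(n - 1, round(3 * fs))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  if (!is.null(band[1]) && !is.na(band[1]) && band[1] > 0) {
    W <- round(0.443 * fs / band[1])
    W <- min(W + (W + 1) %% 2, 2 * length(xp) %/% 2 - 1)
    ma <- as.numeric(stats::filter(xp, rep(1 / W, W), sides = 2))
    if (anyNA(ma)) {   # very short streams: extend the edge values
      ok <- which(!is.na(ma))
      ma[seq_len(ok[1] - 1)] <- ma[ok[1]]
      ma[seq(ok[length(ok)] + 1, length.out = length(ma) - ok[length(ok)])] <-
        ma[ok[length(ok)]]
    }
    xp <- xp - ma
  }
  if (length(band) > 1 && !is.na(band[2]) && band[2] < fs / 2) {
    bt <- signal::butter(2, band[2] / (fs / 2), type = "low")
    xp <- signal::filtfilt(bt, xp)
  }
  xp[(pad + 1):(pad + n)]
}

# Alternating-extrema segmentation with amplitude hysteresis: the engine
# shared by exercise repetition counting and breath-cycle segmentation.
# A reversal is committed only after the signal retraces `h` from the
# running extremum; extrema are placed at the first sample attaining the
# running extremum. Returns alternating extrema (type -1 trough, +1 peak).
hysteresis_extrema <- function(x, h) {
  n <- length(x)
  idx <- integer(0)
  type <- integer(0)
  dir <- 0L
  min_v <- max_v <- x[1]
  min_i <- max_i <- 1L
  for (i in seq_len(n)) {
    xi <- x[i]
    if (xi > max_v) { max_v <- xi; max_i <- i }
    if (xi < min_v) { min_v <- xi; min_i <- i }
    if (dir <= 0L && xi - min_v >= h) {
      idx <- c(idx, min_i); type <- c(type, -1L)
      dir <- 1L
      max_v <- xi; max_i <- i
    } else if (dir >= 0L && max_v - xi >= h) {
      idx <- c(idx, max_i); type <- c(type, 1L)
      dir <- -1L
      min_v <- xi; min_i <- i
    }
  }
  # close a trailing trough so the final cycle is not lost: after the last
  # committed peak the descent has already retraced h (that is what
  # committed the peak), so the running minimum is a genuine trough
  if (dir == -1L) {
    idx <- c(idx, min_i); type <- c(type, -1L)
  }
  list(idx = idx, type = type)
}

extrema_to_cycles <- function(x, t, ext, axis) {
  cycles <- tibble::tibble(start_time = numeric(0), peak_time = numeric(0),
                           end_time = numeric(0), amplitude = numeric(0),
                           rise_duration = numeric(0),
                           fall_duration = numeric(0),
                           dominant_axis = character(0), period = numeric(0))
  k <- which(ext$type == -1L)
  for (j in k) {
    if (j + 2 > length(ext$idx)) break
    if (ext$type[j + 1] != 1L || ext$type[j + 2] != -1L) next
    i1 <- ext$idx[j]; ip <- ext$idx[j + 1]; i2 <- ext$idx[j + 2]
    cycles <- dplyr::bind_rows(cycles, tibble::tibble(
      start_time = t[i1], peak_time = t[ip], end_time = t[i2],
      amplitude = x[ip] - (x[i1] + x[i2]) / 2,
      rise_duration = t[ip] - t[i1],
      fall_duration = t[i2] - t[ip],
      dominant_axis = axis,
      period = t[i2] - t[i1]
    ))
  }
  cycles
}

#' Parameterize a sawtooth-like exercise waveform
#'
#' Selects the dominant axis (largest variance in the 0.2-3 Hz cadence
#' band), band-passes it, and segments cycles at alternating extrema with
#' amplitude hysteresis: a cycle is accepted only when its peak-to-trough
#' excursion exceeds a floor derived from the movement activity energy
#' threshold. Cycles are chronological and non-overlapping; each carries its
#' extrema times, amplitude and rise/fall durations.
#'
#' @param stream an acceleration stream (`t, ax, ay, az`), at least 2 s.
#' @param config a [detector_config()].
#' @return A tibble of cycles: `start_time`, `peak_time`, `end_time`,
#'   `amplitude`, `rise_duration`, `fall_duration`, `dominant_axis`,
#'   `period`.
#' @examples
#' s <- gen_exercise("biceps_curl", n_reps = 6, noise_sd = 0, seed = 5)$stream
#' nrow(parameterize_sawtooth(s))
#' @export
parameterize_sawtooth <- function(stream, config = detector_config()) {
  stream <- as_accel_stream(stream)
  fs <- stream_fs(stream)
  if (nrow(stream) < 2 * fs) {
    stop("parameterize_sawtooth: stream must span at least 2 s",
         call. = FALSE)
  }
  sel <- lapply(c(x = "ax", y = "ay", z = "az"), function(col) {
    bandpass(stream[[col]], fs, SAW_SELECT_BAND_HZ)
  })
  power <- vapply(sel, stats::var, numeric(1))
  axis <- names(which.max(power))
  x <- bandpass(stream[[paste0("a", axis)]], fs, SAW_BAND_HZ)
  ext <- hysteresis_extrema(x, hysteresis_floor(config))
  extrema_to_cycles(x, stream$t, ext, axis)
}

# band-passed dynamic acceleration combined across axes (actigraphy
# "vector magnitude"): the movement intensity signal behind activity
# counts and the resting exclusion
dynamic_vm <- function(stream, fs) {
  b <- lapply(c("ax", "ay", "az"), function(col) {
    bandpass(stream[[col]], fs, SAW_BAND_HZ)
  })
  sqrt(b[[1]]^2 + b[[2]]^2 + b[[3]]^2)
}

# measured feature vector of a cycle train
cycle_features <- function(cycles) {
  list(axis = names(which.max(table(cycles$dominant_axis))),
       period = stats::median(cycles$period),
       amp = stats::median(cycles$amplitude),
       asym = stats::median(cycles$rise_duration / cycles$period))
}

# template bank measured on noiseless generator exemplars, so that the
# classifier compares like with like (band-pass filtering attenuates the
# nominal template amplitudes); memoised per session
the <- new.env(parent = emptyenv())
template_bank <- function(config = detector_config()) {
  if (!is.null(the$bank)) return(the$bank)
  tpl <- exercise_templates()
  feats <- purrr::map_dfr(seq_len(nrow(tpl)), function(i) {
    row <- tpl[i, ]
    ls <- if (row$category == "static_exercise") {
      gen_exercise(row$kind, n_reps = 6, noise_sd = 0, seed = 1000 + i)
    } else {
      gen_exercise(row$kind, duration = 12 * row$period, noise_sd = 0,
                   seed = 1000 + i)
    }
    cy <- parameterize_sawtooth(ls$stream, config)
    f <- cycle_features(cy)
    tibble::tibble(kind = row$kind, region = row$region, axis = f$axis,
                   period = f$period, amp = f$amp, asym = f$asym)
  })
  the$bank <- feats
  feats
}

#' Identify the activity being performed
#'
#' Nearest-template classification of a cycle train: the measured feature
#' vector (dominant axis, median cycle period, median amplitude, rise/fall
#' asymmetry) is compared to a bank of per-exercise reference features, and
#' the closest exercise wins. Axis disagreement is heavily penalized;
#' period and amplitude enter on a log scale. Used as a cross-check of the
#' user-selected exercise, not as the counting gate.
#'
#' @param stream an acceleration stream containing at least 3 cycles.
#' @param config a [detector_config()].
#' @return A one-row tibble: `kind`, `region` (`total`, `upper` or `lower`),
#'   `distance`.
#' @examples
#' s <- gen_exercise("knee_extension", n_reps = 6, noise_sd = 0, seed = 2)
#' classify_activity(s$stream)
#' @export
classify_activity <- function(stream, config = detector_config()) {
  cycles <- parameterize_sawtooth(stream, config)
  if (nrow(cycles) < 3) {
    stop("classify_activity: insufficient data (need at least 3 cycles, ",
         "got ", nrow(cycles), ")", call. = FALSE)
  }
  f <- cycle_features(cycles)
  bank <- template_bank(config)
  d <- (bank$axis != f$axis) * 10 +
    abs(log(bank$period / f$period)) +
    abs(log(bank$amp / f$amp)) +
    2 * abs(bank$asym - f$asym)
  i <- which.min(d)
  tibble::tibble(kind = bank$kind[i], region = bank$region[i],
                 distance = d[i])
}

#' Count exercise repetitions
#'
#' Counts accepted sawtooth cycles for a user-selected exercise. Cycles must
#' fall within exercise-specific period bounds (0.45-2.2 times the template
#' cadence), and cycles whose peak lies in a resting segment (1 s windowed
#' energy below the resting threshold) are excluded. For walking the count
#' is steps; for cycling, pedal strokes.
#'
#' @param stream an acceleration stream.
#' @param exercise the exercise being performed (user-selected), one of
#'   [exercise_templates()]`$kind`.
#' @param config a [detector_config()].
#' @return A `rep_count` list: `n_repetitions`, `exercise`, `cycles`
#'   (accepted cycles tibble), `n_rejected_period`, `n_rejected_rest`.
#' @examples
#' s <- gen_exercise("biceps_curl", n_reps = 6, noise_sd = 0, seed = 5)
#' count_repetitions(s$stream, "biceps_curl")$n_repetitions
#' @export
count_repetitions <- function(stream, exercise, config = detector_config()) {
  tpl <- exercise_templates()
  row <- tpl[tpl$kind == exercise, ]
  if (nrow(row) != 1) {
    stop("count_repetitions: unknown exercise `", exercise, "`",
         call. = FALSE)
  }
  stream <- as_accel_stream(stream)
  cycles <- parameterize_sawtooth(stream, config)
  in_period <- cycles$period >= 0.45 * row$period &
    cycles$period <= 2.2 * row$period
  # resting exclusion: a cycle peaking inside a low-energy segment is not a
  # repetition (between-set rest, sensor idling). Energy here is the mean
  # squared dynamic vector magnitude over a 1 s window, in m^2/s^4.
  fs <- stream_fs(stream)
  vm2 <- dynamic_vm(stream, fs)^2
  e <- as.numeric(stats::filter(vm2, rep(1 / REST_ENERGY_WINDOW,
                                         REST_ENERGY_WINDOW), sides = 2))
  e[is.na(e)] <- vm2[is.na(e)]
  peak_idx <- pmax(1, pmin(nrow(stream),
                           round((cycles$peak_time - stream$t[1]) * fs) + 1))
  active <- e[peak_idx] >= config$resting_energy_threshold
  keep <- in_period & active
  structure(
    list(n_repetitions = sum(keep), exercise = exercise,
         cycles = cycles[keep, , drop = FALSE],
         n_rejected_period = sum(!in_period),
         n_rejected_rest = sum(in_period & !active)),
    class = "rep_count"
  )
}

#' @export
print.rep_count <- function(x, ...) {
  cat(sprintf("<rep_count> %s: %d repetition(s)", x$exercise,
              x$n_repetitions))
  if (x$n_rejected_period + x$n_rejected_rest > 0) {
    cat(sprintf(" (%d rejected by period bounds, %d by resting exclusion)",
                x$n_rejected_period, x$n_rejected_rest))
  }
  cat("\n")
  invisible(x)
}

#' Repetition-count precision
#'
#' Precision of a repetition count against ground truth, in percent:
#' `100 * (1 - |counted - true| / true)`.
#'
#' @param counted counted repetitions.
#' @param true true repetitions (> 0).
#' @return precision in percent (100 = exact).
#' @export
rep_precision <- function(counted, true) {
  stopifnot(all(true > 0))
  100 * (1 - abs(counted - true) / true)
}

#' Estimate metabolic expenditure
#'
#' Converts the vest accelerometry into instantaneous and accumulated
#' metabolic expenditure. The stream is cut into 10 s epochs; each epoch's
#' activity counts are the mean band-passed (0.2-3 Hz) dynamic vector
#' magnitude, mapped linearly to MET (anchored at 1 MET for rest and 3.5
#' MET at the reference walking level) and floored at 1 MET when the epoch
#' energy (mean squared dynamic acceleration) is below the resting
#' threshold. Energy rate is
#' `MET * 3.5 * weight / 200` kcal/min; the accumulated expenditure is the
#' trapezoidal time-integral of the rate. Epochs whose net vertical
#' displacement exceeds the ascending threshold are tagged `ascending`
#' (stair/climb intensity).
#'
#' @param stream an acceleration stream.
#' @param profile a [person_profile()]; `weight` is required.
#' @param config a [detector_config()].
#' @return A `met_report`: list with `epochs` (tibble: `t_start`, `t_end`,
#'   `counts`, `met`, `kcal_min`, `ascending`) and `cumulative_kcal`.
#' @examples
#' s <- gen_exercise("walking", duration = 30, noise_sd = 0, seed = 6)
#' estimate_met(s$stream, person_profile(weight = 75.7))$cumulative_kcal
#' @export
estimate_met <- function(stream, profile, config = detector_config()) {
  if (!inherits(profile, "person_profile") || is.na(profile$weight)) {
    stop("estimate_met: profile weight (kg) is required and has no default",
         call. = FALSE)
  }
  stream <- as_accel_stream(stream)
  fs <- stream_fs(stream)
  mag <- stream_magnitude(stream)
  vm <- dynamic_vm(stream, fs)
  av <- mag - FW_G   # vertical (gravity-line) component, unfiltered: the
                     # net epoch displacement lives in the slow content
  n_epoch <- floor(nrow(stream) / (MET_EPOCH_S * fs))
  if (is.na(n_epoch) || n_epoch < 1) {
    return(structure(list(
      epochs = tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                              counts = numeric(0), met = numeric(0),
                              kcal_min = numeric(0), ascending = logical(0)),
      cumulative_kcal = 0, weight = profile$weight), class = "met_report"))
  }
  slope <- (MET_WALK_VALUE - 1) / MET_WALK_ANCHOR
  epochs <- purrr::map_dfr(seq_len(n_epoch), function(k) {
    i0 <- (k - 1) * MET_EPOCH_S * fs + 1
    i1 <- k * MET_EPOCH_S * fs
    seg <- i0:i1
    counts <- mean(vm[seg])
    resting <- mean(vm[seg]^2) < config$resting_energy_threshold
    met <- if (resting) 1 else max(1, 1 + slope * counts)
    vd <- epoch_vdisp(av[seg], fs)
    tibble::tibble(t_start = stream$t[i0], t_end = stream$t[i1],
                   counts = counts, met = met,
                   kcal_min = met * 3.5 * profile$weight / 200,
                   ascending = vd > config$ascending_displacement_threshold)
  })
  # trapezoidal integral of the rate over epoch midpoints, plus the
  # rectangular head/tail halves, equals rate * epoch length summed
  cumulative <- sum(epochs$kcal_min) * MET_EPOCH_S / 60
  structure(list(epochs = epochs, cumulative_kcal = cumulative,
                 weight = profile$weight),
            class = "met_report")
}

# Net vertical displacement of one epoch, with zero-velocity endpoint
# correction (which also cancels any constant acceleration offset). Over a
# 10 s epoch this is indicative rather than metric: slow sensor wander
# integrates twice, so the ascending tag is only trustworthy for
# low-noise epochs.
epoch_vdisp <- function(av, fs) {
  dt <- 1 / fs
  v <- cumsum(av) * dt
  v <- v - seq(0, v[length(v)], length.out = length(v))
  sum(v) * dt
}

#' @export
print.met_report <- function(x, ...) {
  cat(sprintf("<met_report> %d epoch(s), cumulative %.2f kcal\n",
              nrow(x$epochs), x$cumulative_kcal))
  if (nrow(x$epochs) > 0) {
    cat(sprintf("  instantaneous: %.2f-%.2f kcal/min (%.1f-%.1f MET)\n",
                min(x$epochs$kcal_min), max(x$epochs$kcal_min),
                min(x$epochs$met), max(x$epochs$met)))
  }
  invisible(x)
}
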