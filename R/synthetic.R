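# Synthetic signal generators emulating the laboratory validation protocol:
# activities of daily living and simulated falls recorded at the lower back,
# maintenance exercises and breathing recorded at the thorax. All streams are
# sampled at 40 Hz, start at t = 0 and are bit-reproducible given a seed.

FW_FS <- 40
FW_G <- 9.81
# Additive noise is band-limited: white Gaussian noise smoothed with a 3 s
# moving average and rescaled so its marginal sd equals `noise_sd`. This
# models slow postural sway / baseline wander, the dominant residual
# variability of a body-worn sensor (the MEMS electronic noise floor is
# orders of magnitude smaller).
FW_NOISE_SMOOTH <- 121L

smooth_noise <- function(n, sd, L = FW_NOISE_SMOOTH) {
  if (sd <= 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n + 2L * L, sd = sd * sqrt(L))
  sm <- stats::filter(w, rep(1 / L, L), sides = 2)
  as.numeric(sm[(L + 1):(L + n)])
}

add_noise3 <- function(ax, ay, az, noise_sd) {
  n <- length(ax)
  list(ax = ax + smooth_noise(n, noise_sd),
       ay = ay + smooth_noise(n, noise_sd),
       az = az + smooth_noise(n, noise_sd))
}

raised_cos <- function(u) (1 - cos(pi * u)) / 2        # 0 -> 1
hann_pulse <- function(u) sin(pi * pmin(pmax(u, 0), 1))^2

# One asymmetric smooth sawtooth cycle: trough (-amp/2) at u = 0 and u = 1,
# peak (+amp/2) at u = rise_frac.
saw_cycle <- function(u, amp, rise_frac) {
  ifelse(u < rise_frac,
         -0.5 * amp * cos(pi * u / rise_frac),
         0.5 * amp * cos(pi * (u - rise_frac) / (1 - rise_frac)))
}

#' Catalogue of activity kinds
#'
#' All activity kinds known to the platform: the five fall-free activities
#' and three fall types of the fall-detector validation sequence, the fifteen
#' static maintenance exercises, and the two locomotion exercises. Each kind
#' belongs to exactly one category (`fall`, `fall_free_adl`,
#' `static_exercise`, `locomotion`); exercises additionally carry the body
#' region they train (`total`, `upper`, `lower`).
#'
#' @return A tibble with columns `kind`, `category`, `region`.
#' @examples
#' activity_kinds()
#' @export
activity_kinds <- function() {
  dplyr::bind_rows(
    tibble::tibble(kind = c("stairs_up", "stairs_down", "pick_up_object",
                            "sit_down"),
                   category = "fall_free_adl", region = NA_character_),
    tibble::tibble(kind = c("fall_knees", "fall_from_chair", "fall_from_bed"),
                   category = "fall", region = NA_character_),
    exercise_templates()[, c("kind", "category", "region")]
  )
}

#' Category of an activity kind
#'
#' @param kind activity kind string.
#' @return one of `"fall"`, `"fall_free_adl"`, `"static_exercise"`,
#'   `"locomotion"`.
#' @export
activity_category <- function(kind) {
  ak <- activity_kinds()
  i <- match(kind, ak$kind)
  if (anyNA(i)) {
    stop("unknown activity kind: ", paste(kind[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  ak$category[i]
}

#' Exercise waveform templates
#'
#' Kinematic templates for the fifteen static maintenance exercises and the
#' two locomotion exercises: dominant device axis, cycle period (s), cycle
#' amplitude (peak-to-trough, m/s^2), rise fraction of the cycle (movement
#' asymmetry) and body region. These define both the synthetic generator and
#' the nearest-template activity classifier. Periods and amplitudes are
#' stated assumptions in the range typical of elderly maintenance exercise
#' (cycles of 1.6-5 s at 1.8-3.2 m/s^2); walking is 100 steps/min and
#' cycling 60 strokes/min.
#'
#' @return A tibble with columns `kind`, `category`, `region`, `axis`,
#'   `period`, `amp`, `rise_frac`.
#' @export
exercise_templates <- function() {
  tibble::tribble(
    ~kind,                    ~category,         ~region, ~axis, ~period, ~amp, ~rise_frac,
    "walking",                "locomotion",      "total", "x",   0.60,    2.0,  0.50,
    "cycling",                "locomotion",      "total", "z",   1.00,    1.5,  0.50,
    "costal_expansion",       "static_exercise", "upper", "y",   4.00,    1.8,  0.50,
    "biceps_curl",            "static_exercise", "upper", "x",   3.00,    2.6,  0.40,
    "arm_raise",              "static_exercise", "upper", "x",   3.50,    3.0,  0.45,
    "arm_flexion",            "static_exercise", "upper", "y",   2.50,    2.4,  0.40,
    "overhead_bend",          "static_exercise", "upper", "y",   4.50,    2.8,  0.55,
    "shoulder_blade_squeeze", "static_exercise", "upper", "y",   3.00,    1.9,  0.60,
    "body_inclination",       "static_exercise", "upper", "y",   5.00,    3.2,  0.50,
    "knee_extension",         "static_exercise", "lower", "z",   3.00,    2.2,  0.35,
    "marching_in_place",      "static_exercise", "lower", "x",   1.60,    2.5,  0.50,
    "chair_push_ups",         "static_exercise", "lower", "x",   2.20,    3.0,  0.60,
    "knee_flexion",           "static_exercise", "lower", "z",   2.60,    2.0,  0.45,
    "side_leg_raise",         "static_exercise", "lower", "z",   3.40,    2.6,  0.50,
    "plantar_flexion",        "static_exercise", "lower", "z",   1.80,    1.8,  0.50,
    "hip_flexion",            "static_exercise", "lower", "z",   2.80,    2.8,  0.40,
    "hip_extension",          "static_exercise", "lower", "z",   3.20,    2.4,  0.60
  )
}

time_grid <- function(duration) {
  n <- round(duration * FW_FS)
  (seq_len(n) - 1) / FW_FS
}

finish_accel <- function(t, ax, ay, az, noise_sd, channel, kind, labels,
                         truth, seed) {
  s <- add_noise3(ax, ay, az, noise_sd)
  stream <- tibble::tibble(t = t, ax = s$ax, ay = s$ay, az = s$az)
  new_labeled_stream(stream, channel, kind, labels, truth, seed)
}

# ---- activities of daily living (fall-detector site, lower back) ------------

#' Generate a fall-free activity of daily living
#'
#' Produces a 40 Hz triaxial acceleration stream at the fall-detector site
#' (lower back, device x axis along the trunk). Fall-free activities are
#' modeled as orientation sway and smooth posture transitions: the
#' acceleration magnitude stays near gravity with bounded transients, no
#' sustained vertical-to-horizontal posture change occurs, and the
#' ground-truth fall list is empty.
#'
#' @param kind one of `"walking"`, `"stairs_up"`, `"stairs_down"`,
#'   `"pick_up_object"`, `"sit_down"`.
#' @param duration stream duration in seconds (> 0).
#' @param noise_sd marginal sd of the additive band-limited noise, m/s^2.
#' @param seed integer seed; identical arguments reproduce the stream.
#' @return A `labeled_stream` with an accelerometry stream, activity labels
#'   and truth (`falls` empty; for locomotion also `step_times` and
#'   `cadence_spm`).
#' @examples
#' ls <- gen_adl("walking", duration = 20, noise_sd = 0, seed = 1)
#' range(sqrt(ls$stream$ax^2 + ls$stream$ay^2 + ls$stream$az^2))
#' @export
gen_adl <- function(kind, duration, noise_sd = 0, seed = 1) {
  ok <- c("walking", "stairs_up", "stairs_down", "pick_up_object", "sit_down")
  if (!(is.character(kind) && length(kind) == 1 && kind %in% ok)) {
    stop("gen_adl: `kind` must be a fall-free activity (one of ",
         paste(ok, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("gen_adl: `duration` must be > 0", call. = FALSE)
  }
  withr::with_seed(seed, {
    t <- time_grid(duration)
    n <- length(t)
    truth <- list(falls = numeric(0))
    theta <- numeric(n)   # trunk tilt, rad (0 = upright)
    mag <- rep(FW_G, n)   # acceleration magnitude profile

    if (kind %in% c("walking", "stairs_up", "stairs_down")) {
      period <- if (kind == "walking") 0.60 else 1.10
      theta_max <- if (kind == "walking") 0.07 else 0.09
      pitch <- switch(kind, walking = 0, stairs_up = 0.05, stairs_down = -0.05)
      theta <- pitch + theta_max * sin(2 * pi * t / period)
      step_times <- seq(0, max(t), by = period)
      truth$step_times <- step_times
      truth$cadence_spm <- 60 / period
    } else if (kind == "pick_up_object") {
      t_bend <- min(3, 0.6 * duration)
      t0 <- max(0.25, (duration - t_bend) / 2)
      tau <- t - t0
      inb <- tau >= 0 & tau <= t_bend
      theta[inb] <- (70 * pi / 180) * sin(pi * tau[inb] / t_bend)^2
      # small reach transient at the bottom of the bend
      mag <- mag + 1.2 * hann_pulse((tau - (t_bend / 2 - 0.25)) / 0.5)
    } else { # sit_down
      t_sit <- 1.5
      t0 <- max(0.25, duration / 2 - t_sit)
      tau <- t - t0
      theta_sit <- 8 * pi / 180
      theta <- theta_sit * raised_cos(pmin(pmax(tau / t_sit, 0), 1))
      # brief seat-contact burst, below the fall energy level
      mag <- mag + 0.6 * hann_pulse((tau - (t_sit - 0.2)) / 0.4)
    }

    labels <- tibble::tibble(start = 0, end = max(t), label = kind)
    finish_accel(t, mag * cos(theta), mag * sin(theta), numeric(n),
                 noise_sd, "accel", kind, labels, truth, seed)
  })
}

# descent/impact shape parameters per fall kind: dip amplitude (m/s^2),
# descent duration (s), impact spike duration (s). The spike amplitude is
# set so that the velocity returns to zero at the end of the impact, which
# puts the peak magnitude in the 35-45 m/s^2 range.
fall_shape <- function(kind) {
  switch(kind,
    fall_knees      = list(A_d = 6.0, T_d = 0.60, T_i = 0.12),
    fall_from_chair = list(A_d = 6.0, T_d = 0.50, T_i = 0.12),
    fall_from_bed   = list(A_d = 6.5, T_d = 0.60, T_i = 0.12),
    stop("gen_fall: `kind` must be a fall activity (one of fall_knees, ",
         "fall_from_chair, fall_from_bed)", call. = FALSE)
  )
}

#' Generate a fall
#'
#' Produces a stream containing exactly one fall: upright posture, a partial
#' free-fall descent (magnitude dip below gravity), a high-energy impact
#' spike whose windowed energy far exceeds the default fall energy
#' threshold, and a final horizontal posture. The gravity vector is rotated
#' from the trunk axis (x) to the z axis during the event, and the magnitude
#' profile doubly integrates to a net downward displacement well below the
#' descending threshold.
#'
#' @param kind one of `"fall_knees"`, `"fall_from_chair"`, `"fall_from_bed"`.
#' @param duration stream duration in seconds; at least 8 s so the impact
#'   has 2 s of context on both sides.
#' @inheritParams gen_adl
#' @return A `labeled_stream`; `truth$falls` holds the single impact time
#'   and `truth$drop_m` the net vertical drop implied by the profile.
#' @examples
#' ls <- gen_fall("fall_knees", duration = 10, noise_sd = 0, seed = 3)
#' stream_truth(ls)$falls
#' @export
gen_fall <- function(kind, duration = 10, noise_sd = 0, seed = 1) {
  if (!(is.character(kind) && length(kind) == 1)) {
    stop("gen_fall: `kind` must be a single fall activity", call. = FALSE)
  }
  shape <- fall_shape(kind)
  if (!is.numeric(duration) || duration < 8) {
    stop("gen_fall: `duration` must be at least 8 s", call. = FALSE)
  }
  withr::with_seed(seed, {
    t <- time_grid(duration)
    n <- length(t)
    A_d <- shape$A_d; T_d <- shape$T_d; T_i <- shape$T_i
    spike <- 2 * (A_d * T_d / 2) / T_i   # zero net velocity change
    t_desc <- duration / 2 - T_i          # descent start
    t_imp <- t_desc + T_d                 # impact start
    peak_time <- t_imp + T_i / 2

    mag <- rep(FW_G, n)
    d <- t >= t_desc & t < t_imp
    mag[d] <- FW_G - A_d * hann_pulse((t[d] - t_desc) / T_d)
    i <- t >= t_imp & t < t_imp + T_i
    mag[i] <- FW_G + spike * hann_pulse((t[i] - t_imp) / T_i)

    # trunk rotates from upright to lying across descent + impact
    theta <- (pi / 2) * raised_cos(pmin(pmax((t - t_desc) / (T_d + T_i), 0), 1))

    # net drop implied by the magnitude profile (trapezoidal double integral)
    ev <- t >= t_desc & t <= t_imp + T_i
    av <- mag[ev] - FW_G
    dt <- 1 / FW_FS
    v <- cumsum(c(0, (utils::head(av, -1) + utils::tail(av, -1)) / 2 * dt))
    drop <- sum((utils::head(v, -1) + utils::tail(v, -1)) / 2 * dt)

    labels <- tibble::tibble(
      start = c(0, t_desc, t_imp + T_i),
      end = c(t_desc, t_imp + T_i, max(t)),
      label = c("upright", kind, "lying")
    )
    truth <- list(falls = peak_time, drop_m = drop, kind = kind)
    finish_accel(t, mag * cos(theta), numeric(n), mag * sin(theta),
                 noise_sd, "accel", kind, labels, truth, seed)
  })
}

# ---- exercises (smart-vest site, thorax) ------------------------------------

#' Generate an exercise accelerometry stream
#'
#' Produces the thorax-worn vest's accelerometry for a static maintenance
#' exercise (an exact number of sawtooth cycles on the exercise's dominant
#' axis) or for locomotion (walking or cycling at the template cadence for a
#' requested duration). One second of rest padding surrounds the cycles.
#'
#' @param kind a static exercise or `"walking"`/`"cycling"`; see
#'   [exercise_templates()].
#' @param n_reps number of repetitions (static exercises; >= 1).
#' @param duration duration of the cyclic phase in seconds (locomotion).
#' @inheritParams gen_adl
#' @return A `labeled_stream`; `truth$reps` is the exact cycle count and
#'   `truth$cycle_times` the per-cycle start/peak/end times.
#' @examples
#' ls <- gen_exercise("biceps_curl", n_reps = 6, noise_sd = 0, seed = 5)
#' stream_truth(ls)$reps
#' @export
gen_exercise <- function(kind, n_reps = NULL, duration = NULL, noise_sd = 0,
                         seed = 1) {
  tpl <- exercise_templates()
  row <- tpl[tpl$kind == kind, ]
  if (nrow(row) != 1) {
    stop("gen_exercise: `kind` must be a static exercise or walking/cycling",
         call. = FALSE)
  }
  if (row$category == "static_exercise") {
    if (is.null(n_reps) && is.numeric(duration)) {
      n_reps <- floor(duration / row$period)
    }
    if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
      stop("gen_exercise: `n_reps` must be a whole number >= 1 for static ",
           "exercises", call. = FALSE)
    }
    n_cycles <- as.integer(n_reps)
  } else {
    if (!is.numeric(duration) || duration <= 0) {
      stop("gen_exercise: `duration` must be > 0 for walking/cycling",
           call. = FALSE)
    }
    n_cycles <- as.integer(round(duration / row$period))
    if (n_cycles < 1) {
      stop("gen_exercise: `duration` shorter than one cycle", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    pad <- 1
    span <- 2 * pad + n_cycles * row$period
    t <- time_grid(span)
    n <- length(t)
    tau <- t - pad
    u <- (tau %% row$period) / row$period
    wave <- saw_cycle(u, row$amp, row$rise_frac)
    wave[tau < 0 | tau >= n_cycles * row$period] <- -row$amp / 2

    ax <- rep(FW_G, n); ay <- numeric(n); az <- numeric(n)
    if (row$axis == "x") ax <- ax + wave
    if (row$axis == "y") ay <- ay + wave
    if (row$axis == "z") az <- az + wave

    starts <- pad + (seq_len(n_cycles) - 1) * row$period
    truth <- list(
      reps = n_cycles,
      cycle_times = tibble::tibble(start = starts,
                                   peak = starts + row$rise_frac * row$period,
                                   end = starts + row$period),
      period = row$period, dominant_axis = row$axis
    )
    labels <- tibble::tibble(start = pad, end = pad + n_cycles * row$period,
                             label = kind)
    finish_accel(t, ax, ay, az, noise_sd, "accel", kind, labels, truth, seed)
  })
}

# ---- respiration ------------------------------------------------------------

#' Generate a controlled-breathing waveform
#'
#' Produces the vest's capacitance-proportional respiratory amplitude for a
#' programmed sequence of respiratory rates. Each cycle is a raised-cosine
#' inspiration (40% of the cycle, rising amplitude) followed by a
#' raised-cosine expiration; cycle period is 60/rate seconds. The ground
#' truth stores every inspiration/expiration boundary.
#'
#' @param pattern the programmed protocol: a data frame (or list of
#'   `c(rate, n)` pairs) with columns `rate` (breaths/min, within 4-60) and
#'   `n_cycles` (>= 1).
#' @param noise_sd marginal sd of additive band-limited noise, in amplitude
#'   units (the noiseless cycle has unit amplitude).
#' @param seed integer seed.
#' @return A `labeled_stream` with channel `"resp"`; `truth$breaths` has one
#'   row per cycle (`insp_start`, `insp_end`, `exp_end`) and
#'   `truth$segments` one row per programmed rate.
#' @examples
#' ls <- gen_breathing(data.frame(rate = 6, n_cycles = 3), noise_sd = 0)
#' nrow(stream_truth(ls)$breaths)
#' @export
gen_breathing <- function(pattern, noise_sd = 0, seed = 1) {
  if (is.list(pattern) && !is.data.frame(pattern)) {
    pattern <- do.call(rbind, lapply(pattern, function(p) {
      data.frame(rate = p[[1]], n_cycles = p[[2]])
    }))
  }
  if (!is.data.frame(pattern) || !all(c("rate", "n_cycles") %in% names(pattern))) {
    stop("gen_breathing: `pattern` needs columns rate and n_cycles",
         call. = FALSE)
  }
  if (any(pattern$rate < 4 | pattern$rate > 60)) {
    stop("gen_breathing: rates must lie within [4, 60] breaths/min",
         call. = FALSE)
  }
  if (any(pattern$n_cycles < 1 | pattern$n_cycles != round(pattern$n_cycles))) {
    stop("gen_breathing: `n_cycles` must be whole numbers >= 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    rise_frac <- 0.4
    periods <- rep(60 / pattern$rate, pattern$n_cycles)
    starts <- cumsum(c(0, utils::head(periods, -1)))
    total <- sum(periods)
    # include the closing sample at t = total so the final expiration ends
    # on a trough sample and the last cycle keeps its exact period
    t <- c(time_grid(total), total)
    cyc <- pmin(findInterval(t, starts), length(periods))
    u <- pmin((t - starts[cyc]) / periods[cyc], 1)
    amp <- ifelse(u < rise_frac, raised_cos(u / rise_frac),
                  1 - raised_cos((u - rise_frac) / (1 - rise_frac)))
    amp <- amp + smooth_noise(length(t), noise_sd)

    seg_n <- pattern$n_cycles
    seg_start <- starts[cumsum(c(1, utils::head(seg_n, -1)))]
    seg_end <- c(utils::tail(seg_start, -1), total)
    truth <- list(
      breaths = tibble::tibble(insp_start = starts,
                               insp_end = starts + rise_frac * periods,
                               exp_end = starts + periods),
      segments = tibble::tibble(rate = pattern$rate, n_cycles = seg_n,
                                start = seg_start, end = seg_end)
    )
    labels <- tibble::tibble(start = seg_start, end = seg_end,
                             label = paste0("rate=", pattern$rate))
    stream <- tibble::tibble(t = t, amplitude = amp)
    new_labeled_stream(stream, "resp", "controlled_breathing", labels, truth,
                       seed)
  })
}

#' The controlled-breathing ramp pattern
#'
#' The programmed protocol used in validation: the rate starts at 6
#' breaths/min and increases stepwise to 30 breaths/min.
#'
#' @param n_cycles cycles per rate step.
#' @return A data frame usable as the `pattern` of [gen_breathing()].
#' @export
breathing_ramp_pattern <- function(n_cycles = 3) {
  data.frame(rate = c(6, 10, 12, 15, 20, 30), n_cycles = n_cycles)
}

# ---- full validation protocol ----------------------------------------------

protocol_activity_plan <- function() {
  tibble::tribble(
    ~activity,         ~duration,
    "walking",         12,
    "fall_knees",      10,
    "stairs_up",        9,
    "fall_from_chair", 10,
    "stairs_down",      9,
    "pick_up_object",   7,
    "fall_from_bed",   10,
    "sit_down",         7
  )
}

#' Generate the full fall-validation protocol
#'
#' Replicates the laboratory sequence: each simulated subject performs, per
#' repetition, the five fall-free activities interleaved with the three fall
#' activities. Subject anthropometrics are drawn from the volunteer
#' population (age 38 +/- 6.2 y, height 175 +/- 4.8 cm, weight
#' 75.7 +/- 5.3 kg).
#'
#' @param subjects number of simulated subjects (>= 1).
#' @param repetitions sequence repetitions per subject (>= 1).
#' @inheritParams gen_adl
#' @return A tibble with one row per activity instance: `subject`,
#'   `repetition`, `activity`, `category`, and a `stream` list-column of
#'   `labeled_stream` objects. Subject profiles are attached as the
#'   `"profiles"` attribute.
#' @examples
#' prot <- gen_protocol_sequence(1, 1, noise_sd = 0, seed = 10)
#' table(prot$category)
#' @export
gen_protocol_sequence <- function(subjects, repetitions, noise_sd = 0.3,
                                  seed = 1) {
  if (!is.numeric(subjects) || subjects < 1 ||
      !is.numeric(repetitions) || repetitions < 1) {
    stop("gen_protocol_sequence: `subjects` and `repetitions` must be >= 1",
         call. = FALSE)
  }
  plan <- protocol_activity_plan()
  grid <- tidyr::expand_grid(subject = seq_len(subjects),
                             repetition = seq_len(repetitions),
                             plan)
  withr::with_seed(seed, {
    profiles <- tibble::tibble(
      subject = seq_len(subjects),
      age = stats::rnorm(subjects, 38, 6.2),
      height = stats::rnorm(subjects, 175, 4.8),
      weight = stats::rnorm(subjects, 75.7, 5.3)
    )
    stream_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  })
  grid$category <- activity_category(grid$activity)
  grid$stream <- purrr::pmap(
    list(grid$activity, grid$duration, stream_seeds, grid$category),
    function(activity, duration, s, category) {
      if (category == "fall") {
        gen_fall(activity, duration, noise_sd, seed = s)
      } else {
        gen_adl(activity, duration, noise_sd, seed = s)
      }
    }
  )
  out <- grid[, c("subject", "repetition", "activity", "category", "stream")]
  attr(out, "profiles") <- profiles
  out
}
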