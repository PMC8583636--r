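test_that("sawtooth parameterization recovers exact cycle counts", {
  s <- gen_exercise("biceps_curl", n_reps = 6, noise_sd = 0, seed = 5)$stream
  cy <- parameterize_sawtooth(s)
  expect_identical(nrow(cy), 6L)
  expect_true(all(cy$start_time < cy$peak_time & cy$peak_time < cy$end_time))
  expect_true(all(cy$amplitude > 0))
  expect_true(all(diff(cy$start_time) > 0))
  expect_identical(unique(cy$dominant_axis), "x")
  expect_identical(nrow(parameterize_sawtooth(const_stream(400))), 0L)
  expect_error(parameterize_sawtooth(const_stream(60)), "2 s")
})

test_that("sub-hysteresis wiggles are rejected", {
  ls <- gen_exercise("arm_raise", n_reps = 6, noise_sd = 0, seed = 9)
  s <- ls$stream
  # inject a wiggle well below the hysteresis floor mid-way through a fall
  # flank; brute-force extrema enumeration of the clean signal says the
  # count must stay at 6
  mid <- round(nrow(s) / 2)
  bump <- 0.3 * sin(pi * seq(0, 1, length.out = 9))
  s$ax[mid:(mid + 8)] <- s$ax[mid:(mid + 8)] + bump
  cy <- parameterize_sawtooth(s)
  expect_identical(nrow(cy), 6L)
})

test_that("counting is invariant under time shift and amplitude scaling", {
  base <- gen_exercise("knee_extension", n_reps = 5, noise_sd = 0, seed = 4)
  n0 <- count_repetitions(base$stream, "knee_extension")$n_repetitions
  expect_identical(n0, 5L)
  shifted <- dplyr::mutate(base$stream, t = t + 123.4)
  expect_identical(count_repetitions(shifted, "knee_extension")$n_repetitions,
                   n0)
  for (k in c(1.3, 2, 4)) {
    scaled <- base$stream
    g_ax <- mean(scaled$ax[1:20])
    scaled$az <- scaled$az * k   # scale the dominant-axis excursion
    expect_identical(
      count_repetitions(scaled, "knee_extension")$n_repetitions, n0)
  }
})

test_that("all seventeen activity kinds recover truth noiselessly", {
  tpl <- exercise_templates()
  for (i in seq_len(nrow(tpl))) {
    kind <- tpl$kind[i]
    ls <- if (tpl$category[i] == "static_exercise") {
      gen_exercise(kind, n_reps = 6, noise_sd = 0, seed = 40 + i)
    } else {
      gen_exercise(kind, duration = 60, noise_sd = 0, seed = 40 + i)
    }
    rc <- count_repetitions(ls$stream, kind)
    expect_identical(rc$n_repetitions, stream_truth(ls)$reps)
    cl <- classify_activity(ls$stream)
    expect_identical(cl$kind, kind)
    expect_identical(cl$region, tpl$region[i])
  }
})

test_that("region mapping separates total, upper and lower body", {
  tpl <- exercise_templates()
  expect_setequal(tpl$kind[tpl$region == "total"], c("walking", "cycling"))
  expect_identical(sum(tpl$region == "upper"), 7L)
  expect_identical(sum(tpl$region == "lower"), 8L)
  expect_true(all(c("biceps_curl", "arm_flexion", "overhead_bend") %in%
                    tpl$kind[tpl$region == "upper"]))
  expect_true(all(c("knee_extension", "knee_flexion", "chair_push_ups",
                    "hip_flexion", "hip_extension") %in%
                    tpl$kind[tpl$region == "lower"]))
})

test_that("too few cycles raise an insufficient-data error", {
  s <- gen_exercise("biceps_curl", n_reps = 2, noise_sd = 0, seed = 3)$stream
  expect_error(classify_activity(s), "nsufficient")
})

test_that("a stream that is all rest counts zero repetitions", {
  s <- const_stream(800)
  expect_identical(count_repetitions(s, "biceps_curl")$n_repetitions, 0L)
  ls <- gen_adl("walking", 20, 0.05, seed = 1)   # sub-floor sway only
  expect_identical(count_repetitions(ls$stream, "biceps_curl")$n_repetitions,
                   0L)
})

test_that("step and stroke precision meet the reported figures under noise", {
  prec <- function(kind) {
    mean(vapply(1:20, function(s) {
      ls <- gen_exercise(kind, duration = 60, noise_sd = 0.3, seed = s)
      rc <- count_repetitions(ls$stream, kind)
      rep_precision(rc$n_repetitions, stream_truth(ls)$reps)
    }, numeric(1)))
  }
  expect_gte(prec("walking"), 98.3)
  expect_gte(prec("cycling"), 97.5)
})

test_that("resting expenditure converts weight to kcal/min exactly", {
  rest <- const_stream(20 * FS)
  m <- estimate_met(rest, person_profile(weight = 75.7))
  expect_identical(nrow(m$epochs), 2L)
  expect_true(all(m$epochs$met == 1))
  expect_equal(unique(m$epochs$kcal_min), 1.0 * 3.5 * 75.7 / 200)
  expect_equal(unique(m$epochs$kcal_min), 1.32475)
  # streams shorter than one epoch accumulate nothing
  short <- estimate_met(const_stream(100), person_profile(weight = 75.7))
  expect_identical(short$cumulative_kcal, 0)
  expect_identical(nrow(short$epochs), 0L)
})

test_that("active epochs exceed resting expenditure and accumulate monotonically", {
  ls <- gen_exercise("walking", duration = 60, noise_sd = 0.3, seed = 6)
  m <- estimate_met(ls$stream, person_profile(weight = 75.7))
  active <- m$epochs[m$epochs$counts > 0.2, ]
  expect_gt(nrow(active), 3)
  expect_true(all(active$met > 1))
  expect_true(all(active$kcal_min > 1.32475))
  # cumulative expenditure is the integral of the rate: non-decreasing and
  # additive over concatenation
  expect_gte(m$cumulative_kcal, 0)
  half1 <- estimate_met(ls$stream[1:(30 * FS), ], person_profile(weight = 75.7))
  rest2 <- ls$stream[(30 * FS + 1):nrow(ls$stream), ]
  half2 <- estimate_met(rest2, person_profile(weight = 75.7))
  expect_equal(half1$cumulative_kcal + half2$cumulative_kcal,
               m$cumulative_kcal, tolerance = 0.15)
})

test_that("epochs with a net climb are tagged ascending", {
  # constructed upward displacement: sustained lift acceleration profile
  # inside one epoch (rise then brake), net +0.3 m by double integration
  n <- 20 * FS
  t <- (seq_len(n) - 1) / FS
  av <- 0.9 * sin(pi * pmin(pmax((t - 11) / 1, 0), 1))^2 -
    0.9 * sin(pi * pmin(pmax((t - 13) / 1, 0), 1))^2
  s <- tibble::tibble(t = t, ax = G + av, ay = 0.3 * sin(2 * pi * t),
                      az = 0)
  m <- estimate_met(s, person_profile(weight = 70))
  expect_identical(m$epochs$ascending, c(FALSE, TRUE))
})
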