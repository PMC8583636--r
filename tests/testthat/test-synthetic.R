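test_that("generators are deterministic in (parameters, seed)", {
  gens <- list(
    function(s) gen_adl("walking", 15, 0.3, seed = s),
    function(s) gen_fall("fall_knees", 10, 0.3, seed = s),
    function(s) gen_exercise("biceps_curl", n_reps = 4, noise_sd = 0.3, seed = s),
    function(s) gen_breathing(data.frame(rate = 12, n_cycles = 3), 0.05, seed = s)
  )
  for (g in gens) {
    expect_identical(g(7)$stream, g(7)$stream)
    expect_false(isTRUE(all.equal(g(7)$stream, g(8)$stream)))
  }
  p1 <- gen_protocol_sequence(1, 1, 0.3, seed = 5)
  p2 <- gen_protocol_sequence(1, 1, 0.3, seed = 5)
  expect_identical(p1$stream[[3]]$stream, p2$stream[[3]]$stream)
})

test_that("generator preconditions reject invalid arguments", {
  expect_error(gen_adl("fall_knees", 10), "fall-free")
  expect_error(gen_adl("walking", 0), "duration")
  expect_error(gen_fall("walking", 10), "fall activity")
  expect_error(gen_exercise("knee_extension", n_reps = 0), "n_reps")
  expect_error(gen_exercise("no_such_exercise", n_reps = 3), "kind")
  expect_error(gen_breathing(data.frame(rate = 0, n_cycles = 3)), "4, 60")
  expect_error(gen_breathing(data.frame(rate = 75, n_cycles = 3)), "4, 60")
  expect_error(gen_protocol_sequence(0, 3), ">= 1")
})

test_that("labels lie within the stream span and truth counts match requests", {
  streams <- list(
    gen_adl("sit_down", 8, 0.2, seed = 1),
    gen_fall("fall_from_bed", 10, 0.2, seed = 2),
    gen_exercise("arm_raise", n_reps = 5, noise_sd = 0.2, seed = 3),
    gen_breathing(data.frame(rate = c(6, 12), n_cycles = c(2, 3)), 0.02, 4)
  )
  for (ls in streams) {
    lab <- ls$labels
    expect_true(all(lab$start < lab$end))
    expect_gte(min(lab$start), min(ls$stream$t))
    expect_lte(max(lab$end), max(ls$stream$t) + 1e-9)
    if (nrow(lab) > 1) {
      expect_true(all(lab$start[-1] >= lab$end[-nrow(lab)] - 1e-9))
    }
  }
  expect_identical(stream_truth(streams[[2]])$falls,
                   stream_truth(streams[[2]])$falls[1])
  expect_identical(stream_truth(streams[[3]])$reps, 5L)
  expect_identical(nrow(stream_truth(streams[[4]])$breaths), 5L)
})

test_that("stationary segments average to gravity", {
  ls <- gen_fall("fall_knees", 10, 0.3, seed = 11)
  mag <- sqrt(ls$stream$ax^2 + ls$stream$ay^2 + ls$stream$az^2)
  pre <- ls$stream$t < 2          # upright, before any movement
  post <- ls$stream$t > 8         # lying still
  expect_equal(mean(mag[pre]), G, tolerance = 0.05)
  expect_equal(mean(mag[post]), G, tolerance = 0.05)
})

test_that("fall streams satisfy the fall signature and ADL streams do not", {
  cfg <- detector_config()
  for (kind in c("fall_knees", "fall_from_chair", "fall_from_bed")) {
    ls <- gen_fall(kind, 10, 0, seed = 21)
    tr <- stream_truth(ls)
    expect_length(tr$falls, 1)
    expect_lt(tr$drop_m, cfg$descending_displacement_threshold)
    # post-impact gravity projection on the trunk axis is far below the
    # vertical posture threshold
    post <- ls$stream[ls$stream$t > tr$falls + 1, ]
    expect_lt(mean(post$ax), cfg$vertical_posture_threshold)
    expect_gt(max(signal_energy(ls$stream)), cfg$fall_energy_threshold)
  }
  ls <- gen_adl("sit_down", 8, 0, seed = 22)
  expect_length(stream_truth(ls)$falls, 0)
  # one brief sub-threshold energy burst, final posture vertical
  e <- signal_energy(ls$stream)
  expect_gt(max(e), 0)
  expect_lt(max(e), detector_config()$fall_energy_threshold)
  fin <- ls$stream[ls$stream$t > max(ls$stream$t) - 1, ]
  expect_identical(classify_posture(fin), "vertical")
})

test_that("walking follows the generator step schedule", {
  ls <- gen_adl("walking", 60, 0.3, seed = 2)
  tr <- stream_truth(ls)
  expect_equal(tr$cadence_spm, 100)
  expect_equal(tr$step_times, seq(0, max(ls$stream$t), by = 0.6))
})

test_that("exercise streams carry exactly the requested cycles", {
  ls1 <- gen_exercise("knee_extension", n_reps = 1, noise_sd = 0, seed = 7)
  expect_identical(stream_truth(ls1)$reps, 1L)
  ls6 <- gen_exercise("biceps_curl", n_reps = 6, noise_sd = 0, seed = 5)
  ct <- stream_truth(ls6)$cycle_times
  expect_identical(nrow(ct), 6L)
  expect_true(all(ct$start < ct$peak & ct$peak < ct$end))
  # locomotion: cycle count = cadence x duration
  lw <- gen_exercise("walking", duration = 60, noise_sd = 0.3, seed = 6)
  expect_identical(stream_truth(lw)$reps, 100L)
  lc <- gen_exercise("cycling", duration = 60, noise_sd = 0.3, seed = 6)
  expect_identical(stream_truth(lc)$reps, 60L)
})

test_that("breathing cycles have period 60/rate and the ramp shrinks them", {
  ls <- gen_breathing(data.frame(rate = 6, n_cycles = 3), 0, seed = 8)
  b <- stream_truth(ls)$breaths
  expect_equal(b$exp_end - b$insp_start, rep(10, 3))
  ramp <- gen_breathing(data.frame(rate = c(6, 12, 30), n_cycles = 3), 0, 9)
  rb <- stream_truth(ramp)$breaths
  expect_identical(nrow(rb), 9L)
  periods <- rb$exp_end - rb$insp_start
  expect_true(all(diff(periods) <= 1e-9))
  expect_equal(unique(round(periods, 6)), c(10, 5, 2))
})

test_that("the protocol sequence has the right composition and profiles", {
  prot <- gen_protocol_sequence(3, 3, noise_sd = 0, seed = 10)
  expect_identical(nrow(prot), 72L)
  expect_identical(sum(prot$category == "fall"), 27L)
  expect_identical(sum(prot$category != "fall"), 45L)
  falls <- sum(vapply(prot$stream, function(s) length(s$truth$falls), 1L))
  expect_identical(falls, 27L)
  prof <- attr(prot, "profiles")
  expect_identical(nrow(prof), 3L)
  expect_true(all(prof$weight > 50 & prof$weight < 100))
  expect_true(all(prof$height > 155 & prof$height < 195))
  one <- gen_protocol_sequence(1, 1, noise_sd = 0, seed = 10)
  expect_identical(nrow(one), 8L)
  expect_identical(sum(one$category == "fall"), 3L)
})

test_that("activity kinds map to exactly one category", {
  ak <- activity_kinds()
  expect_identical(anyDuplicated(ak$kind), 0L)
  expect_identical(nrow(ak), 24L)   # 4 adl + 3 falls + 15 static + 2 locomotion
  expect_setequal(unique(ak$category),
                  c("fall", "fall_free_adl", "static_exercise", "locomotion"))
  expect_identical(activity_category("fall_knees"), "fall")
  expect_identical(activity_category("walking"), "locomotion")
  expect_error(activity_category("jumping"), "unknown")
})
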