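test_that("configuration objects validate their fields", {
  expect_error(motor_config(fast_speed = 0.1, slow_speed = 0.2), "fast_speed")
  expect_error(motor_config(pressure_tolerance = 0), "tolerance")
  expect_error(protocol_config(n_steps = 1), "n_steps")
  expect_error(protocol_config(fixed_step_pressures = c(40, 40, 90)),
               "increasing")
  expect_error(divide_pressure_range(100, 100), "degenerate")
})

test_that("range division matches the worked examples", {
  expect_equal(divide_pressure_range(25, 245, 5), c(25, 80, 135, 190, 245))
  expect_equal(divide_pressure_range(40, 240, 5), c(40, 90, 140, 190, 240))
  expect_equal(divide_pressure_range(0, 1, 2), c(0, 1))
})

wide <- noiseless_subject(p_first = 25, p_peak = 135, p_last = 265)
ex_wide <- run_existing_protocol(wide, seed = 5)

test_that("the fixed protocol hits every fixed step within tolerance", {
  expect_length(ex_wide$recordings, 5)
  app <- vapply(ex_wide$recordings, `[[`, numeric(1), "app")
  expect_true(all(abs(app - c(40, 90, 140, 190, 240)) <= 2))
  expect_true(all(vapply(ex_wide$recordings, `[[`, logical(1),
                         "within_tolerance")))
  expect_false(ex_wide$partial)
  # each dwell is exactly dwell * sampling_rate samples
  expect_true(all(vapply(ex_wide$recordings,
                         function(r) length(r$samples), numeric(1)) == 5000))
})

test_that("a pulseless subject still completes the fixed protocol", {
  silent <- subject_profile(a_max = 0, noise_sd = 0)
  res <- run_existing_protocol(silent, seed = 2)
  expect_length(res$recordings, 5)
  an <- analyze_acquisition(res)
  expect_equal(an$y, rep(0, 5))
})

test_that("motor travel matches the compliance closed form", {
  lin <- noiseless_subject(stiffness = 50, gamma = 1, p_last = 280)
  res <- run_existing_protocol(lin, seed = 1)
  got <- abs(res$step5_position - res$step1_position)
  want <- (depth_for_pressure(lin, 240) - depth_for_pressure(lin, 40)) * 200
  expect_lte(abs(got - want), 1)
  expect_equal(moving_distance(res), got / 200)
})

test_that("moving distance is pulses over resolution", {
  r1 <- ex_wide
  r1$step1_position <- 1000L; r1$step5_position <- 1800L
  expect_equal(moving_distance(r1), 4)
  r1$step5_position <- 1000L
  expect_equal(moving_distance(r1), 0)
})

test_that("the sweep passes the last perceptible pulse and then stops", {
  p <- noiseless_subject(p_first = 25, p_peak = 135, p_last = 245)
  sw <- run_descent_sweep(p, seed = 3)
  slow <- sw[sw$phase == "slow-sweep", ]
  end_pressure <- baseline_pressure(p, max(slow$motor_position_pulses) / 200)
  expect_gt(end_pressure, 245)
  expect_lte(end_pressure, 300)
  expect_true(all(diff(sw$motor_position_pulses) >= 0))

  # termination = last detected peak + silence window; re-detection on the
  # truncated trace may pick up one extra marginal beat near the new edge,
  # so the observed gap lies within [silence - 2 beat periods, silence]
  peaks <- pulsedepth:::sweep_detect(slow$pressure_mmHg, slow$time_s,
                                     protocol_config())$peaks
  term_gap <- max(slow$time_s) - max(peaks$time)
  beat_period <- 60 / p$heart_rate
  expect_lte(term_gap, 2 + 0.01)
  expect_gte(term_gap, 2 - 2 * beat_period)
  env_at_last <- envelope_amplitude(p, peaks$baseline[nrow(peaks)])
  expect_gte(env_at_last, 0.8)   # stopped within a beat of the threshold
})

test_that("a pulseless subject aborts the sweep", {
  silent <- subject_profile(a_max = 0, noise_sd = 0)
  expect_error(run_descent_sweep(silent, seed = 1), "no pulse detected")
})

test_that("sweep endpoint recovery is limited only by beat quantization", {
  cfg <- cohort_config(noise_sd = 0)
  cohort <- make_cohort(6, seed = 11, config = cfg)
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    r <- determine_pressure_range(run_descent_sweep(p, seed = 100 + i))
    # error bounded by ~1.5 beat-quantization steps at each endpoint
    tol_start <- 1.5 * beat_pressure_step(p, p$p_first) + 1
    tol_end <- 1.5 * beat_pressure_step(p, p$p_last) + 1
    expect_lt(abs(r[["p_start"]] - p$p_first), tol_start)
    expect_lt(abs(r[["p_end"]] - p$p_last), tol_end)
  }
})

test_that("endpoint recovery degrades gracefully under sensor noise", {
  quiet <- noiseless_subject()
  noisy <- subject_profile(p_first = 25, p_peak = 135, p_last = 245,
                           noise_sd = 0.5)
  r0 <- determine_pressure_range(run_descent_sweep(quiet, seed = 3))
  r5 <- determine_pressure_range(run_descent_sweep(noisy, seed = 3))
  expect_lt(max(abs(r5 - r0)), 10)
})

test_that("the adaptive protocol measures its own range on ascent", {
  p <- noiseless_subject(p_first = 25, p_peak = 135, p_last = 245)
  res <- run_proposed_protocol(p, seed = 3)
  expect_length(res$recordings, 5)
  expect_false(is.null(res$sweep))

  # step pressures are exactly the 5-fold division of the sweep's range
  rng <- determine_pressure_range(res$sweep)
  steps <- divide_pressure_range(rng[["p_start"]], rng[["p_end"]], 5)
  targets <- vapply(res$recordings, `[[`, numeric(1), "target_pressure")
  expect_equal(targets, steps)
  app <- vapply(res$recordings, `[[`, numeric(1), "app")
  expect_true(all(abs(app - steps) <= 2))
  # ascent order: step 5 was recorded first
  t_start <- vapply(res$recordings, function(r) r$times[1], numeric(1))
  expect_equal(order(t_start), 5:1)
})

test_that("protocols are deterministic given a seed", {
  p <- subject_profile(p_first = 25, p_peak = 120, p_last = 240,
                       noise_sd = 0.3)
  expect_identical(run_proposed_protocol(p, seed = 17),
                   run_proposed_protocol(p, seed = 17))
  expect_identical(run_existing_protocol(p, seed = 17),
                   run_existing_protocol(p, seed = 17))
})

test_that("wider true ranges travel farther under the adaptive protocol", {
  # true range strictly contains [40, 240]
  for (seed in 1:3) {
    p <- noiseless_subject(p_first = 20 + seed, p_peak = 120 + 10 * seed,
                           p_last = 252 + 4 * seed)
    ex <- run_existing_protocol(p, seed = seed)
    pr <- run_proposed_protocol(p, seed = seed)
    expect_gt(moving_distance(pr), moving_distance(ex))
  }
})

test_that("acquisitions round-trip through CSV + sidecar", {
  p <- subject_profile(p_first = 25, p_peak = 135, p_last = 245,
                       noise_sd = 0.2)
  res <- run_proposed_protocol(p, seed = 8)
  dir <- withr::local_tempdir()
  sidecar <- write_acquisition(res, dir)
  expect_true(file.exists(sidecar))
  expect_length(list.files(dir, pattern = "_step[0-9]+\\.csv$"), 5)
  expect_length(list.files(dir, pattern = "_sweep\\.csv$"), 1)

  back <- read_acquisition(sidecar)
  expect_equal(back$step1_position, res$step1_position)
  a1 <- analyze_acquisition(res)
  a2 <- analyze_acquisition(back)
  expect_equal(a2$cfs, a1$cfs, tolerance = 1e-6)
  expect_equal(a2$moving_distance_mm, a1$moving_distance_mm)
})
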