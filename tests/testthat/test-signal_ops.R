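test_that("detrending removes ramps and constants exactly", {
  t <- seq(0, 30, by = 0.002)
  ramp <- 10 + 6 * t
  out <- detrend_sweep(ramp, t)
  expect_lt(max(abs(out)), 0.01 * diff(range(ramp)))
  expect_lt(max(abs(out)), 1e-9)

  const <- rep(5, 3000)
  expect_equal(as.numeric(detrend_sweep(const, t[1:3000])), rep(0, 3000))

  expect_error(detrend_sweep(1:5, (1:5) / 500), "shorter")
})

test_that("detrending preserves a beat-band oscillation on a ramp", {
  t <- seq(0, 30, by = 0.002)
  ramp <- 10 + 6 * t
  s <- sin(2 * pi * t / 0.4)            # 150 bpm-like component
  out <- detrend_sweep(ramp + s, t)
  interior <- 1500:13500                # clear of edge windows
  rel <- sqrt(mean((out[interior] - s[interior])^2)) / sqrt(mean(s^2))
  expect_lt(rel, 0.05)

  # near zero-mean over windows of whole oscillation periods (> 3 beats)
  for (st in c(2000, 6000, 10000)) {
    w <- out[st:(st + 1999)]            # 4 s = 10 full periods
    expect_lt(abs(mean(w)), 0.05 * sqrt(mean(s^2)))
  }
})

test_that("peak detection matches the brute-force prominence oracle", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(20:80, 1)
    x <- cumsum(rnorm(n))               # rough terrain
    times <- seq_len(n) * 0.1
    min_prom <- runif(1, 0.2, 2)
    min_int <- sample(c(0.1, 0.25, 0.45), 1)
    got <- find_sweep_peaks(x, times, min_prom, min_int)
    want <- oracle_peaks(x, times, min_prom, min_int)
    expect_identical(got$index, as.integer(want))
  }
})

test_that("peak detection handles monotone series and exact ties", {
  t <- (1:50) / 10
  expect_equal(nrow(find_sweep_peaks(seq(1, 5, length.out = 50), t, 0.5, 0.1)),
               0)
  # two identical peaks closer than min_interval: earlier index wins
  x <- c(0, 3, 0, 3, 0)
  got <- find_sweep_peaks(x, (1:5) * 0.1, 1, 0.5)
  expect_equal(got$index, 2L)
})

test_that("a noiseless sweep yields one detected peak per beat", {
  p <- noiseless_subject(heart_rate = 60, p_first = 25, p_peak = 135,
                         p_last = 245)
  # constant-speed descent through a 12-s stretch around mid-envelope
  fs <- 500
  times <- seq_len(12 * fs) / fs
  d0 <- depth_for_pressure(p, 100)
  depth <- d0 + 0.125 * times
  s <- sensor_signal(p, depth, times)
  det <- detrend_sweep(s, times)
  pk <- find_sweep_peaks(as.numeric(det), times, 1, 0.33,
                         baseline = attr(det, "trend"))
  # beats every 1 s; edge beats may fall into detrending edge regions
  expect_true(nrow(pk) %in% c(10, 11, 12))
  expect_true(all(abs(diff(pk$time) - 1) < 0.01))
  # detected peak times sit on the simulated percussion peaks (phase 0.15)
  expect_true(all(abs((pk$time - 0.15) %% 1) < 0.02 |
                    abs((pk$time - 0.15) %% 1 - 1) < 0.02))
})

test_that("first/last peak extraction flags degenerate sweeps", {
  pk <- find_sweep_peaks(c(0, 1, 0, 2, 0, 3, 0), (1:7) / 2, 0.5, 0.1)
  fl <- first_last_peaks(pk)
  expect_equal(fl$first$index, 2L)
  expect_equal(fl$last$index, 6L)
  expect_false(fl$degenerate)

  one <- find_sweep_peaks(c(0, 3, 0), (1:3) / 2, 1, 0.1)
  fl1 <- first_last_peaks(one)
  expect_true(fl1$degenerate)
  expect_identical(fl1$first, fl1$last)

  empty <- find_sweep_peaks(1:10, (1:10) / 2, 1, 0.1)
  expect_error(first_last_peaks(empty), "no peaks")
})

make_rec <- function(profile, pressure, dwell = 10, fs = 500, seed = NULL) {
  times <- seq_len(dwell * fs) / fs
  depth <- rep(depth_for_pressure(profile, pressure), length(times))
  s <- sensor_signal(profile, depth, times, seed = seed)
  pulsedepth:::step_recording(1L, pressure, pressure,
                              round(depth[1] * 200), s, times, fs, TRUE)
}

test_that("beat segmentation finds complete beats with equal amplitudes", {
  p <- noiseless_subject(heart_rate = 60)
  rec <- make_rec(p, p$p_peak)
  beats <- segment_beats(rec)
  expect_true(nrow(beats) %in% 8:10)
  amps <- rec$samples[beats$peak_index] - rec$samples[beats$foot_index]
  # interior beats are exact; beats in the detrender's edge regions can be
  # located a few samples off their true peak
  expect_lt(max(abs(amps - p$a_max)) / p$a_max, 0.03)
  interior <- beats$peak_index > 1500 & beats$peak_index < 3500
  amps_in <- amps[interior]
  expect_lt(max(abs(amps_in - p$a_max)) / p$a_max, 0.005)

  flat <- pulsedepth:::step_recording(1L, 100, 100, 0, rep(100, 5000),
                                      seq_len(5000) / 500, 500, TRUE)
  expect_error(segment_beats(flat), "insufficient beats")
})

test_that("pulse pressure estimates the envelope amplitude", {
  p <- noiseless_subject(heart_rate = 72)
  rec <- make_rec(p, p$p_peak)
  expect_equal(pulse_pressure(rec), p$a_max, tolerance = 0.02)

  silent <- subject_profile(a_max = 0, noise_sd = 0)
  expect_error(pulse_pressure(make_rec(silent, 100)), "insufficient beats")
})

test_that("pulse pressure is noise-robust, shift-invariant, scale-equivariant", {
  p0 <- noiseless_subject(heart_rate = 72)
  rec0 <- make_rec(p0, p0$p_peak)
  y0 <- pulse_pressure(rec0)

  pn <- subject_profile(heart_rate = 72, noise_sd = 0.3)
  ys <- vapply(1:20, function(s) pulse_pressure(make_rec(pn, pn$p_peak,
                                                         seed = s)),
               numeric(1))
  expect_lt(mean(abs(ys - y0) / y0), 0.03)
  expect_lt(max(abs(ys - y0) / y0), 0.06)

  shifted <- rec0
  shifted$samples <- rec0$samples + 37.5
  expect_equal(pulse_pressure(shifted), y0)

  scaled <- rec0
  base <- rec0$target_pressure
  scaled$samples <- base + 1.8 * (rec0$samples - base)
  expect_equal(pulse_pressure(scaled), 1.8 * y0, tolerance = 1e-6)
})
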