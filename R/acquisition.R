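#' Motor and sensor configuration
#'
#' Instrument constants. The printed motor speeds are stored in mm/s: a
#' working range of a few millimetres traversed at metres per second would
#' complete in milliseconds, incompatible with 500-Hz sampling and beat
#' detection, so the fast and slow speeds are interpreted as 1.563 and
#' 0.125 mm/s.
#'
#' @param fast_speed fast descent speed, mm/s.
#' @param slow_speed slow descent / positioning speed, mm/s.
#' @param pulses_per_mm step-motor resolution (default 200 pulses/mm, i.e.
#'   5 um per pulse).
#' @param sampling_rate sensor sampling rate, Hz.
#' @param pressure_tolerance allowed |APP - target| at a step, mmHg.
#' @param contact_pressure baseline pressure (mmHg) that, sustained for
#'   \code{contact_sustain} seconds, ends the fast descent.
#' @param contact_sustain see \code{contact_pressure}; seconds.
#' @return A list of class \code{motor_config}.
#' @export
motor_config <- function(fast_speed = 1.563, slow_speed = 0.125,
                         pulses_per_mm = 200L, sampling_rate = 500,
                         pressure_tolerance = 2,
                         contact_pressure = 5, contact_sustain = 0.02) {
  if (!(fast_speed > slow_speed && slow_speed > 0))
    stop("require fast_speed > slow_speed > 0")
  if (pulses_per_mm <= 0 || sampling_rate <= 0)
    stop("pulses_per_mm and sampling_rate must be positive")
  if (pressure_tolerance <= 0) stop("pressure_tolerance must be positive")
  structure(list(fast_speed = fast_speed, slow_speed = slow_speed,
                 pulses_per_mm = as.integer(pulses_per_mm),
                 sampling_rate = sampling_rate,
                 pressure_tolerance = pressure_tolerance,
                 contact_pressure = contact_pressure,
                 contact_sustain = contact_sustain),
            class = "motor_config")
}

#' Measurement protocol configuration
#'
#' @param n_steps number of pressure steps (>= 2).
#' @param dwell recording duration per step, s.
#' @param fixed_step_pressures the fixed protocol's step pressures, mmHg,
#'   strictly increasing.
#' @param max_pressure safety limit, mmHg; the sweep never exceeds it.
#' @param silence_window sweep termination rule: the sweep ends this many
#'   seconds after the last qualifying beat peak, s.
#' @param min_peak_prominence beat detector prominence threshold, mmHg.
#' @param min_beat_interval beat detector minimum inter-peak interval, s
#'   (0.33 s admits heart rates up to ~180 bpm).
#' @return A list of class \code{protocol_config}.
#' @export
protocol_config <- function(n_steps = 5L, dwell = 10,
                            fixed_step_pressures = c(40, 90, 140, 190, 240),
                            max_pressure = 300, silence_window = 2,
                            min_peak_prominence = 1, min_beat_interval = 0.33) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (dwell <= 0) stop("dwell must be positive")
  if (any(diff(fixed_step_pressures) <= 0))
    stop("fixed_step_pressures must be strictly increasing")
  structure(list(n_steps = as.integer(n_steps), dwell = dwell,
                 fixed_step_pressures = fixed_step_pressures,
                 max_pressure = max_pressure,
                 silence_window = silence_window,
                 min_peak_prominence = min_peak_prominence,
                 min_beat_interval = min_beat_interval),
            class = "protocol_config")
}

step_recording <- function(step_index, target_pressure, app, motor_position,
                           samples, times, sampling_rate, within_tolerance) {
  structure(list(step_index = as.integer(step_index),
                 target_pressure = target_pressure, app = app,
                 motor_position = as.integer(motor_position),
                 samples = samples, times = times,
                 sampling_rate = sampling_rate,
                 within_tolerance = within_tolerance),
            class = "step_recording")
}

acquisition_result <- function(method, subject_id, recordings, sweep = NULL,
                               partial = FALSE, seed = NA_integer_) {
  idx <- vapply(recordings, `[[`, integer(1), "step_index")
  if (anyDuplicated(idx)) stop("duplicate step indices")
  recordings <- recordings[order(idx)]
  structure(list(method = method, subject_id = subject_id,
                 recordings = recordings, sweep = sweep, partial = partial,
                 seed = seed,
                 step1_position = recordings[[1L]]$motor_position,
                 step5_position = recordings[[length(recordings)]]$motor_position),
            class = "acquisition_result")
}

#' @export
print.acquisition_result <- function(x, ...) {
  cat(sprintf("<acquisition_result %s method, subject %s%s>\n", x$method,
              x$subject_id, if (x$partial) ", PARTIAL" else ""))
  for (r in x$recordings)
    cat(sprintf("  step %d: target %7.2f mmHg, APP %7.2f mmHg, motor %d pulses\n",
                r$step_index, r$target_pressure, r$app, r$motor_position))
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: %d samples\n", nrow(x$sweep)))
  invisible(x)
}

# ---- internal protocol mechanics ------------------------------------------

# Fast descent until contact: the contact-pressure crossing plus the sustain
# interval, solved analytically (the compliance is deterministic).
fast_descent <- function(profile, motor) {
  d_cross <- depth_for_pressure(profile, motor$contact_pressure)
  t_contact <- d_cross / motor$fast_speed + motor$contact_sustain
  list(t = t_contact, depth = t_contact * motor$fast_speed)
}

# Move at slow speed to the pulse-quantized depth for a target pressure.
servo_to <- function(profile, motor, t, depth, target_pressure) {
  d_target <- depth_for_pressure(profile, target_pressure)
  pulses <- as.integer(round(d_target * motor$pulses_per_mm))
  d_actual <- pulses / motor$pulses_per_mm
  t <- t + abs(d_actual - depth) / motor$slow_speed
  app <- baseline_pressure(profile, d_actual)
  list(t = t, depth = d_actual, pulses = pulses, app = app,
       ok = abs(app - target_pressure) <= motor$pressure_tolerance)
}

# Record one dwell at a held position, drawing noise from the current stream.
dwell_record <- function(profile, motor, proto, t, sv, step_index,
                         target_pressure) {
  n <- round(proto$dwell * motor$sampling_rate)
  dt <- 1 / motor$sampling_rate
  times <- t + dt * seq_len(n)
  samples <- sensor_signal(profile, rep(sv$depth, n), times, seed = NULL)
  rec <- step_recording(step_index, target_pressure, sv$app, sv$pulses,
                        samples, times, motor$sampling_rate, sv$ok)
  list(rec = rec, t = times[n])
}

# Shared sweep beat detection: detrend, smooth, prominence peaks with the
# hold-down pressure (trend) read at each peak. The prominence threshold is
# raised 4 post-smoothing noise SDs above the configured floor so that noise
# excursions on top of sub-threshold beats do not qualify; on noiseless data
# it reduces to the configured threshold.
sweep_detect <- function(pressures, times, proto, smooth_window = 0.04) {
  det <- detrend_sweep(pressures, times)
  sm <- smooth_signal(as.numeric(det), times, smooth_window)
  thr <- proto$min_peak_prominence + 4 * smoothed_noise_sd(det, sm)
  peaks <- find_sweep_peaks(sm, times, thr, proto$min_beat_interval,
                            baseline = attr(det, "trend"))
  list(detrended = det, smoothed = sm, peaks = peaks, threshold = thr)
}

# ---- protocols -------------------------------------------------------------

#' Run the fixed-range (existing) protocol
#'
#' Fast descent to skin contact, then slow descent stopping at each of the
#' fixed step pressures in ascending order, recording \code{dwell} seconds of
#' signal at each held position. The actual applied pressure (APP) is the
#' baseline pressure at the held motor position. Steps above the safety
#' pressure limit are skipped and the result flagged partial.
#'
#' @param profile a [subject_profile()].
#' @param motor a [motor_config()].
#' @param proto a [protocol_config()].
#' @param seed integer seed; the whole run is deterministic given it.
#' @return An \code{acquisition_result}.
#' @export
run_existing_protocol <- function(profile, motor = motor_config(),
                                  proto = protocol_config(), seed = 1L) {
  with_seed(seed, {
    st <- fast_descent(profile, motor)
    t <- st$t; depth <- st$depth
    recs <- list(); partial <- FALSE
    for (i in seq_along(proto$fixed_step_pressures)) {
      target <- proto$fixed_step_pressures[i]
      if (target > proto$max_pressure) { partial <- TRUE; break }
      sv <- servo_to(profile, motor, t, depth, target)
      dw <- dwell_record(profile, motor, proto, sv$t, sv, i, target)
      recs[[length(recs) + 1L]] <- dw$rec
      t <- dw$t; depth <- sv$depth
    }
    acquisition_result("existing", profile$subject_id, recs, sweep = NULL,
                       partial = partial, seed = seed)
  })
}

# Sweep body shared by run_descent_sweep() and run_proposed_protocol();
# draws from the current RNG stream.
sweep_core <- function(profile, motor, proto) {
  dt <- 1 / motor$sampling_rate
  st <- fast_descent(profile, motor)
  # fast-descent phase, recorded for completeness
  n_fast <- max(1L, floor(st$t / dt))
  t_fast <- dt * seq_len(n_fast)
  d_fast <- t_fast * motor$fast_speed
  s_fast <- sensor_signal(profile, d_fast, t_fast, seed = NULL)
  # slow sweep down to the safety limit
  d_max <- depth_for_pressure(profile, proto$max_pressure)
  n_slow <- floor((d_max - st$depth) / (motor$slow_speed * dt))
  if (n_slow < 2) stop("no room for a slow sweep below the safety limit")
  t_slow <- st$t + dt * seq_len(n_slow)
  d_slow <- st$depth + motor$slow_speed * dt * seq_len(n_slow)
  s_slow <- sensor_signal(profile, d_slow, t_slow, seed = NULL)

  peaks <- sweep_detect(s_slow, t_slow, proto)$peaks
  if (!nrow(peaks)) stop("no pulse detected")
  t_stop <- min(peaks$time[nrow(peaks)] + proto$silence_window,
                t_slow[n_slow])
  keep <- t_slow <= t_stop
  trace <- data.frame(
    time_s = c(t_fast, t_slow[keep]),
    pressure_mmHg = c(s_fast, s_slow[keep]),
    motor_position_pulses = as.integer(round(
      c(d_fast, d_slow[keep]) * motor$pulses_per_mm)),
    phase = c(rep("fast-descent", n_fast), rep("slow-sweep", sum(keep))))
  attr(trace, "subject_id") <- profile$subject_id
  class(trace) <- c("sweep_trace", "data.frame")
  list(trace = trace, t_end = max(t_slow[keep]),
       depth_end = max(d_slow[keep]))
}

#' Run the continuous slow-descent sweep
#'
#' After fast descent to contact, the sensor descends at the slow speed,
#' recording continuously. The sweep ends \code{silence_window} seconds after
#' the last qualifying beat peak, or at the safety pressure limit. Errors if
#' no beat is ever detected.
#'
#' @inheritParams run_existing_protocol
#' @return A \code{sweep_trace} data frame with columns \code{time_s},
#'   \code{pressure_mmHg}, \code{motor_position_pulses}, \code{phase}.
#' @export
run_descent_sweep <- function(profile, motor = motor_config(),
                              proto = protocol_config(), seed = 1L) {
  with_seed(seed, sweep_core(profile, motor, proto))$trace
}

#' Subject-specific pressure range from a sweep
#'
#' Re-detects beat peaks on the slow-sweep portion of the trace and returns
#' the baseline hold-down pressure at the first and the last detected peak --
#' the pressures at which the pulse is sensed first and last.
#'
#' @param sweep a \code{sweep_trace}.
#' @param proto a [protocol_config()] supplying the detector thresholds.
#' @return Named numeric vector \code{c(p_start =, p_end =)}, mmHg.
#' @export
determine_pressure_range <- function(sweep, proto = protocol_config()) {
  stopifnot(inherits(sweep, "sweep_trace"))
  slow <- sweep[sweep$phase == "slow-sweep", , drop = FALSE]
  if (nrow(slow) < 3) stop("sweep contains no slow-sweep samples")
  peaks <- sweep_detect(slow$pressure_mmHg, slow$time_s, proto)$peaks
  if (!nrow(peaks)) stop("no pulse detected in sweep")
  fl <- first_last_peaks(peaks)
  if (fl$degenerate)
    stop("degenerate pressure range: only one beat peak detected")
  p_start <- fl$first$baseline
  p_end <- fl$last$baseline
  if (p_end <= p_start)
    stop("degenerate pressure range: p_end <= p_start")
  c(p_start = p_start, p_end = p_end)
}

#' Divide a pressure range into equal steps
#'
#' @param p_start,p_end range endpoints, mmHg, \code{p_end > p_start}.
#' @param n_steps number of steps (>= 2).
#' @return \code{n_steps} equally spaced pressures with exact endpoints.
#' @export
divide_pressure_range <- function(p_start, p_end, n_steps = 5L) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (p_end <= p_start) stop("degenerate range: p_end must exceed p_start")
  seq(p_start, p_end, length.out = n_steps)
}

#' Run the adaptive (proposed) protocol
#'
#' Runs the slow-descent sweep, determines the subject's own pressure range
#' from the first and last detected beat peaks, divides it into
#' \code{n_steps} equal pressures, then measures the steps on ascent in
#' decreasing-pressure order (motor up), recording \code{dwell} seconds at
#' each. Recordings are re-indexed so step 1 is the lowest pressure.
#'
#' @inheritParams run_existing_protocol
#' @return An \code{acquisition_result} that also carries the sweep trace.
#' @export
run_proposed_protocol <- function(profile, motor = motor_config(),
                                  proto = protocol_config(), seed = 1L) {
  with_seed(seed, {
    sw <- sweep_core(profile, motor, proto)
    rng <- determine_pressure_range(sw$trace, proto)
    steps <- divide_pressure_range(rng[["p_start"]], rng[["p_end"]],
                                   proto$n_steps)
    t <- sw$t_end; depth <- sw$depth_end
    recs <- vector("list", proto$n_steps)
    for (i in rev(seq_along(steps))) {    # ascent: highest pressure first
      sv <- servo_to(profile, motor, t, depth, steps[i])
      dw <- dwell_record(profile, motor, proto, sv$t, sv, i, steps[i])
      recs[[i]] <- dw$rec
      t <- dw$t; depth <- sv$depth
    }
    acquisition_result("proposed", profile$subject_id, recs,
                       sweep = sw$trace, partial = FALSE, seed = seed)
  })
}

#' Step-motor moving distance
#'
#' Motor travel between the first and the last pressure step, the
#' instrument's proxy for pulse depth.
#'
#' @param result an \code{acquisition_result}.
#' @param motor a [motor_config()] supplying the pulses-per-mm resolution.
#' @return Distance in mm.
#' @export
moving_distance <- function(result, motor = motor_config()) {
  stopifnot(inherits(result, "acquisition_result"))
  if (result$partial || is.null(result$step1_position) ||
      is.null(result$step5_position))
    stop("result is missing its first or last step")
  abs(result$step5_position - result$step1_position) / motor$pulses_per_mm
}
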