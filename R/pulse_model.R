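#' Periodic two-bump beat waveform
#'
#' A unit-amplitude periodic waveform on phase \eqn{[0, 1)} built from a
#' percussion bump and a smaller dicrotic bump (wrapped Gaussians), then
#' normalised so that its minimum over one period is exactly 0 and its maximum
#' exactly 1 (to within the resolution of the normalisation grid).
#'
#' @param percussion_center,percussion_width location and width (in phase
#'   units) of the main systolic bump.
#' @param dicrotic_center,dicrotic_width,dicrotic_weight location, width and
#'   relative height of the dicrotic bump.
#' @param grid_n number of grid points used to compute the normalisation
#'   constants.
#' @return An object of class \code{beat_shape}.
#' @seealso [beat_wave()]
#' @export
beat_shape <- function(percussion_center = 0.15, percussion_width = 0.045,
                       dicrotic_center = 0.45, dicrotic_width = 0.09,
                       dicrotic_weight = 0.35, grid_n = 4096L) {
  stopifnot(percussion_width > 0, dicrotic_width > 0, dicrotic_weight >= 0,
            grid_n >= 16L)
  shape <- list(pc = percussion_center, pw = percussion_width,
                dc = dicrotic_center, dw = dicrotic_width,
                dweight = dicrotic_weight)
  grid <- seq(0, 1, length.out = grid_n + 1L)[-(grid_n + 1L)]
  raw <- beat_raw(shape, grid)
  shape$offset <- min(raw)
  shape$scale <- max(raw) - shape$offset
  if (shape$scale <= 0) stop("degenerate beat shape: constant waveform")
  class(shape) <- "beat_shape"
  shape
}

# Unnormalised waveform: two wrapped-Gaussian bumps on the unit circle.
beat_raw <- function(shape, phase) {
  wrap <- function(d) pmin(abs(d), 1 - abs(d))
  p <- phase - floor(phase)
  exp(-(wrap(p - shape$pc))^2 / (2 * shape$pw^2)) +
    shape$dweight * exp(-(wrap(p - shape$dc))^2 / (2 * shape$dw^2))
}

#' Evaluate a beat waveform at given phases
#'
#' @param shape a [beat_shape()] object.
#' @param phase numeric vector of phases; the waveform has period exactly 1.
#' @return Values in \eqn{[0, 1]}.
#' @export
beat_wave <- function(shape, phase) {
  stopifnot(inherits(shape, "beat_shape"))
  (beat_raw(shape, phase) - shape$offset) / shape$scale
}

#' Synthetic wrist subject
#'
#' A generative model of one radial pulse measurement site. The pulse-pressure
#' amplitude as a function of hold-down pressure \eqn{p} is a
#' threshold-anchored asymmetric Gaussian bump: amplitude equals
#' \code{a_max} at \code{p_peak} and \code{a_thresh} at both \code{p_first}
#' and \code{p_last}, with a separate Gaussian width on each side of the peak
#' so that both boundary conditions hold exactly. Tissue compliance linking
#' motor travel to hold-down pressure is a power law
#' \eqn{p = k (d - d_0)^\gamma} above the skin-contact depth \eqn{d_0}.
#'
#' Subjects with a thicker subcutaneous layer (higher BMI) present deeper:
#' larger contact depth and an amplitude peak at higher pressure.
#'
#' @param subject_id character label.
#' @param heart_rate beats per minute, in (30, 180).
#' @param p_first hold-down pressure (mmHg) at which the pulse first becomes
#'   detectable (amplitude = \code{a_thresh}).
#' @param p_peak pressure (mmHg) of maximum pulse amplitude;
#'   \code{p_first < p_peak < p_last}.
#' @param p_last pressure (mmHg) at which the pulse vanishes (occlusion).
#' @param a_max peak pulse-pressure amplitude (mmHg). \code{a_max = 0} denotes
#'   a pulseless subject.
#' @param a_thresh detectability floor (mmHg); amplitude at \code{p_first} and
#'   \code{p_last}. Must be below \code{a_max} unless \code{a_max = 0}.
#' @param contact_depth motor travel (mm) at which the sensor touches skin.
#' @param stiffness compliance coefficient \eqn{k} (mmHg/mm^gamma).
#' @param gamma compliance nonlinearity exponent.
#' @param noise_sd sensor noise standard deviation (mmHg).
#' @param bmi body-mass index (kg/m^2), carried for reporting.
#' @param beat a [beat_shape()] waveform.
#' @return An object of class \code{subject_profile}.
#' @export
subject_profile <- function(subject_id = "S01", heart_rate = 72,
                            p_first = 30, p_peak = 130, p_last = 250,
                            a_max = 8, a_thresh = 1,
                            contact_depth = 2, stiffness = 40, gamma = 1.2,
                            noise_sd = 0.3, bmi = 22, beat = beat_shape()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!(heart_rate > 30 && heart_rate < 180))
    stop("heart_rate must be in (30, 180) beats/min")
  if (!(p_first < p_peak && p_peak < p_last))
    stop("require p_first < p_peak < p_last")
  if (p_first < 0) stop("p_first must be non-negative")
  if (a_max < 0 || a_thresh <= 0)
    stop("require a_max >= 0 and a_thresh > 0")
  if (a_max > 0 && a_thresh >= a_max)
    stop("require a_thresh < a_max for a pulsatile subject")
  if (contact_depth < 0) stop("contact_depth must be non-negative")
  if (stiffness <= 0 || gamma <= 0) stop("stiffness and gamma must be > 0")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(subject_id = subject_id, heart_rate = heart_rate,
                 p_first = p_first, p_peak = p_peak, p_last = p_last,
                 a_max = a_max, a_thresh = a_thresh,
                 contact_depth = contact_depth, stiffness = stiffness,
                 gamma = gamma, noise_sd = noise_sd, bmi = bmi, beat = beat),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s>\n", x$subject_id))
  cat(sprintf("  heart rate   : %.1f bpm\n", x$heart_rate))
  cat(sprintf("  pulse range  : [%.1f, %.1f] mmHg, peak %.1f (amp %.2f mmHg)\n",
              x$p_first, x$p_last, x$p_peak, x$a_max))
  cat(sprintf("  compliance   : p = %.1f (d - %.2f mm)^%.2f\n",
              x$stiffness, x$contact_depth, x$gamma))
  cat(sprintf("  noise sd     : %.2f mmHg   BMI %.2f kg/m^2\n",
              x$noise_sd, x$bmi))
  invisible(x)
}

#' Cohort generator configuration
#'
#' Constants of the cohort generative model, exposed so the BMI couplings and
#' physiological ranges are configuration rather than hard-coded values.
#' Defaults emulate the reference study population: resting adults, subject
#' pulse ranges roughly 16--280 mmHg wide enough that step1-to-step5 motor
#' travel lands in the 2--6 mm band, and overweight subjects (BMI >= 25)
#' presenting a deep (sinking-prone) amplitude peak above their range
#' midpoint.
#'
#' @param heart_rate_range resting heart rate range, beats/min.
#' @param p_first_range range for the first-detectable pressure, mmHg.
#' @param range_width_range range for \code{p_last - p_first}, mmHg.
#' @param a_max_range peak amplitude range, mmHg.
#' @param a_thresh detectability floor, mmHg (matched to the default peak
#'   detector prominence so that detection ends where the pulse "vanishes").
#' @param travel_range target full-range motor travel, mm; the compliance
#'   coefficient is solved per subject so travel falls here.
#' @param gamma compliance exponent.
#' @param noise_sd sensor noise, mmHg.
#' @param bmi_overweight BMI cutoff (kg/m^2) at which the amplitude peak
#'   crosses to above the range midpoint.
#' @param peak_bmi_slope linear map from (BMI - bmi_overweight) to the peak
#'   offset from the range midpoint, mmHg per kg/m^2.
#' @param peak_jitter multiplicative jitter range applied to that offset.
#' @param contact_depth_base,contact_depth_bmi_slope linear map from BMI to
#'   skin-contact depth, mm and mm per kg/m^2 (centred at BMI 22).
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(heart_rate_range = c(60, 95),
                          p_first_range = c(18, 38),
                          range_width_range = c(205, 245),
                          a_max_range = c(5, 10),
                          a_thresh = 1,
                          travel_range = c(2.8, 5.8),
                          gamma = 1.2,
                          noise_sd = 0.3,
                          bmi_overweight = 25,
                          peak_bmi_slope = 6,
                          peak_jitter = c(0.7, 1.3),
                          contact_depth_base = 2,
                          contact_depth_bmi_slope = 0.1) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws \code{n} [subject_profile()]s deterministically from \code{seed}.
#' Subjects with BMI at or above the overweight cutoff get an amplitude peak
#' strictly above their range midpoint (deep, sinking-prone), mirroring the
#' thicker subcutaneous tissue of overweight subjects; the rest peak below it.
#'
#' @param n number of subjects, >= 1.
#' @param seed integer RNG seed.
#' @param bmi_range BMI range (kg/m^2) to draw from.
#' @param config a [cohort_config()].
#' @return A list of \code{subject_profile} objects.
#' @export
make_cohort <- function(n, seed = 1L, bmi_range = c(18.5, 30.5),
                        config = cohort_config()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  if (bmi_range[1] > bmi_range[2]) stop("inverted bmi_range")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      bmi <- runif(1, bmi_range[1], bmi_range[2])
      hr <- runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
      p_first <- runif(1, config$p_first_range[1], config$p_first_range[2])
      width <- runif(1, config$range_width_range[1],
                     config$range_width_range[2])
      p_last <- p_first + width
      mid <- p_first + width / 2
      off <- config$peak_bmi_slope * (bmi - config$bmi_overweight) *
        runif(1, config$peak_jitter[1], config$peak_jitter[2])
      p_peak <- mid + off
      # keep the peak safely interior while preserving its side of the midpoint
      lo <- p_first + 0.12 * width
      hi <- p_last - 0.12 * width
      p_peak <- min(max(p_peak, lo), hi)
      if (bmi >= config$bmi_overweight) p_peak <- max(p_peak, mid + 1)
      a_max <- runif(1, config$a_max_range[1], config$a_max_range[2])
      cd <- config$contact_depth_base +
        config$contact_depth_bmi_slope * (bmi - 22)
      travel <- runif(1, config$travel_range[1], config$travel_range[2])
      k <- solve_stiffness(p_first, p_last, travel, config$gamma)
      subject_profile(subject_id = sprintf("S%02d", i), heart_rate = hr,
                      p_first = p_first, p_peak = p_peak, p_last = p_last,
                      a_max = a_max, a_thresh = config$a_thresh,
                      contact_depth = cd, stiffness = k,
                      gamma = config$gamma, noise_sd = config$noise_sd,
                      bmi = bmi)
    })
  })
}

# Compliance coefficient k such that depth(p_last) - depth(p_first) = travel.
solve_stiffness <- function(p_first, p_last, travel, gamma) {
  f <- function(k) (p_last / k)^(1 / gamma) - (p_first / k)^(1 / gamma) - travel
  stats::uniroot(f, c(1e-3, 1e4), tol = 1e-10)$root
}

#' Pulse-amplitude envelope
#'
#' Pulse-pressure amplitude at hold-down pressure \code{p}: a unimodal
#' asymmetric Gaussian bump with value \code{a_max} at \code{p_peak} and
#' \code{a_thresh} at both \code{p_first} and \code{p_last}. Values below
#' \code{a_thresh} are returned as-is; detectability is decided downstream by
#' the peak detector.
#'
#' @param profile a [subject_profile()].
#' @param p hold-down pressure(s), mmHg, >= 0.
#' @return Amplitude(s) in mmHg.
#' @export
envelope_amplitude <- function(profile, p) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(p < 0)) stop("p must be non-negative")
  if (profile$a_max == 0) return(rep(0, length(p)))
  s <- envelope_sigmas(profile)
  sig <- ifelse(p < profile$p_peak, s[["left"]], s[["right"]])
  profile$a_max * exp(-(p - profile$p_peak)^2 / (2 * sig^2))
}

#' Envelope Gaussian widths
#'
#' The left/right Gaussian widths implied by the boundary conditions
#' amplitude(\code{p_first}) = amplitude(\code{p_last}) = \code{a_thresh}.
#'
#' @param profile a [subject_profile()].
#' @return Named numeric vector \code{c(left =, right =)} in mmHg.
#' @export
envelope_sigmas <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"), profile$a_max > 0)
  z <- sqrt(2 * log(profile$a_max / profile$a_thresh))
  c(left = (profile$p_peak - profile$p_first) / z,
    right = (profile$p_last - profile$p_peak) / z)
}

#' Static pressure from motor depth
#'
#' Power-law tissue compliance: 0 below the skin-contact depth, then
#' \eqn{k (d - d_0)^\gamma}.
#'
#' @param profile a [subject_profile()].
#' @param depth motor travel(s), mm, >= 0.
#' @return Baseline hold-down pressure(s), mmHg.
#' @seealso [depth_for_pressure()], its inverse above contact.
#' @export
baseline_pressure <- function(profile, depth) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(depth < 0)) stop("depth must be non-negative")
  x <- pmax(depth - profile$contact_depth, 0)
  profile$stiffness * x^profile$gamma
}

#' Motor depth for a target static pressure
#'
#' Inverse of [baseline_pressure()] above the contact point.
#'
#' @param profile a [subject_profile()].
#' @param p hold-down pressure(s), mmHg, >= 0.
#' @return Depth(s) in mm.
#' @export
depth_for_pressure <- function(profile, p) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(p < 0)) stop("p must be non-negative")
  profile$contact_depth + (p / profile$stiffness)^(1 / profile$gamma)
}

#' Simulated sensor signal along a depth trajectory
#'
#' Each sample is baseline pressure plus the beat waveform scaled by the
#' amplitude envelope evaluated at that baseline, plus i.i.d. Gaussian noise:
#' \deqn{s(t) = b(d(t)) + A(b(d(t))) \cdot w(\phi(t)) + \epsilon(t)}
#' with beat phase \eqn{\phi(t) = t \cdot HR / 60}.
#'
#' @param profile a [subject_profile()].
#' @param depth_trajectory motor depth (mm) at each sample.
#' @param times sample times (s), strictly increasing and uniformly spaced.
#' @param seed integer seed for the noise draw, or \code{NULL} to draw from
#'   the current RNG stream (used internally by the protocol engines, which
#'   seed once per run).
#' @return Numeric vector of sensor pressures, mmHg.
#' @export
sensor_signal <- function(profile, depth_trajectory, times, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  n <- length(times)
  if (length(depth_trajectory) != n)
    stop("trajectory/times length mismatch")
  if (n > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (diff(range(dt)) > 1e-9 * max(dt))
      stop("times must be uniformly spaced")
  }
  base <- baseline_pressure(profile, depth_trajectory)
  # no skin contact, no pulse transmission
  env <- envelope_amplitude(profile, base) * (base > 0)
  phase <- times * profile$heart_rate / 60
  sig <- base + env * beat_wave(profile$beat, phase)
  if (profile$noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(n, 0, profile$noise_sd)
             else with_seed(seed, rnorm(n, 0, profile$noise_sd))
    sig <- sig + noise
  }
  sig
}
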