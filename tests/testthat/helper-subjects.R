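# Shared fixtures: deterministic test subjects and an independent
# brute-force peak-detection oracle.

noiseless_subject <- function(p_first = 25, p_peak = 135, p_last = 245,
                              heart_rate = 72, a_max = 8, stiffness = 40,
                              gamma = 1.2, contact_depth = 2, ...) {
  subject_profile(p_first = p_first, p_peak = p_peak, p_last = p_last,
                  heart_rate = heart_rate, a_max = a_max,
                  stiffness = stiffness, gamma = gamma,
                  contact_depth = contact_depth, noise_sd = 0, ...)
}

symmetric_subject <- function(p_first = 25, p_last = 245, ...) {
  noiseless_subject(p_first = p_first, p_peak = (p_first + p_last) / 2,
                    p_last = p_last, ...)
}

# Brute-force prominence peak detector: direct definition, naive scans.
oracle_peaks <- function(x, times, min_prom, min_int) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand <- c(cand, i)
  qual <- integer(0)
  for (i in cand) {
    hi_l <- which(x[seq_len(i - 1)] > x[i])
    lb <- if (length(hi_l)) min(x[max(hi_l):i]) else min(x[1:i])
    hi_r <- which(x[(i + 1):n] > x[i]) + i
    rb <- if (length(hi_r)) min(x[i:min(hi_r)]) else min(x[i:n])
    if (x[i] - max(lb, rb) >= min_prom) qual <- c(qual, i)
  }
  sel <- integer(0)
  for (i in qual[order(-x[qual], qual)]) {
    if (!length(sel) || all(abs(times[i] - times[sel]) >= min_int))
      sel <- c(sel, i)
  }
  sort(sel)
}

# Pressure risen during one beat interval at pressure p: the sweep's
# intrinsic endpoint resolution for a given subject.
beat_pressure_step <- function(profile, p, slow_speed = 0.125) {
  x <- depth_for_pressure(profile, p) - profile$contact_depth
  slope <- profile$gamma * p / x
  slope * slow_speed * 60 / profile$heart_rate
}
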