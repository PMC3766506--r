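#' Remove the slow pressure ramp from a sweep recording
#'
#' Two-stage baseline estimation, windows tied to an expected beat period.
#' A plain running median cannot separate small beats from the sweep's
#' pressure ramp: within one window the ramp rises by several mmHg, the
#' windowed samples are value-ordered almost exactly by time, and the median
#' ends up tracking the beats themselves. The ramp is therefore removed
#' first with a centred moving average over 1.5 beat periods (exact for
#' locally linear trends; edges use odd-reflection padding, which preserves
#' lines), and a running median over 3 beat periods then tracks the residual
#' slow level of the flattened signal, where its robustness to the
#' short-duty-cycle asymmetric beat waveform does the intended work.
#' Topographic peak prominence measured on the output is insensitive to the
#' beat-mean offset both stages share.
#'
#' @param pressures sensor pressures, mmHg, uniformly sampled.
#' @param times sample times, s.
#' @param beat_period_prior expected beat period in seconds. The default,
#'   0.8 s, is the period at the centre of a 40--150 bpm heart-rate prior.
#' @return The detrended series; the removed trend (the baseline-pressure
#'   estimate) is attached as \code{attr(, "trend")}.
#' @export
detrend_sweep <- function(pressures, times, beat_period_prior = 0.8) {
  n <- length(pressures)
  stopifnot(length(times) == n)
  if (n < 3) stop("series shorter than the detrending window")
  dt <- (times[n] - times[1]) / (n - 1)
  odd_window <- function(w) {
    k <- max(3L, as.integer(round(w / dt)))
    if (k %% 2L == 0L) k <- k + 1L
    k
  }
  k <- odd_window(1.5 * beat_period_prior)
  km <- min(odd_window(3 * beat_period_prior),
            if (n %% 2L == 0L) n - 1L else n)
  if (k > n) stop("series shorter than the detrending window")
  ma <- reflect_ma(pressures, k)
  flat <- pressures - ma
  trend <- ma + as.numeric(runmed(flat, km, endrule = "median"))
  out <- pressures - trend
  attr(out, "trend") <- trend
  out
}

# Centred moving average with odd-reflection padding (preserves lines).
reflect_ma <- function(x, k) {
  n <- length(x)
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  if (k < 3L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(2 * x[1] - x[(h + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - h)])
  cs <- c(0, cumsum(xp))
  (cs[(k + 1L):(n + k)] - cs[1:n]) / k
}

#' Suppress sensor noise before peak detection
#'
#' Short centred moving average (default 40 ms) applied to a detrended
#' series. At 500 Hz this attenuates wide-band sensor noise by about a
#' factor of four while leaving the much wider beat bumps nearly intact, so
#' that noise excursions do not reach the peak detector's prominence
#' threshold.
#'
#' @param x detrended series.
#' @param times sample times, s.
#' @param smooth_window window length, s.
#' @return Smoothed series.
#' @export
smooth_signal <- function(x, times, smooth_window = 0.04) {
  n <- length(x)
  if (n < 3 || smooth_window <= 0) return(x)
  dt <- (times[n] - times[1]) / (n - 1)
  k <- as.integer(round(smooth_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L) return(x)
  out <- reflect_ma(x, k)
  attr(out, "k") <- k
  out
}

#' Detect beat peaks by topographic prominence
#'
#' Finds strict local maxima, computes each peak's topographic prominence
#' (height above the higher of the two cols separating it from higher
#' terrain), keeps peaks with prominence at least \code{min_prominence}, and
#' greedily enforces a minimum inter-peak interval: conflicts keep the higher
#' peak, exact height ties keep the earlier index.
#'
#' @param detrended detrended pressure series, mmHg.
#' @param times sample times, s.
#' @param min_prominence minimum topographic prominence, mmHg, > 0.
#' @param min_interval minimum inter-peak interval, s.
#' @param baseline optional series of baseline (trend) pressures from which
#'   the hold-down pressure at each peak is read.
#' @return A \code{peak_list}: data frame with columns \code{index},
#'   \code{time}, \code{amplitude} (detrended height) and \code{baseline}
#'   (hold-down pressure at the peak, or \code{NA}). Possibly zero rows.
#' @export
find_sweep_peaks <- function(detrended, times, min_prominence = 1,
                             min_interval = 0.33, baseline = NULL) {
  stopifnot(min_prominence > 0, length(times) == length(detrended))
  x <- as.numeric(detrended)
  n <- length(x)
  empty <- data.frame(index = integer(), time = numeric(),
                      amplitude = numeric(), baseline = numeric())
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3) return(empty)
  # strict rise on the left, non-rise on the right; plateaus keep their first
  # index only
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(empty)
  # greedy interval enforcement: highest first, earlier index breaks ties
  ord <- keep[order(-x[keep], keep)]
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) || all(abs(times[i] - times[acc]) >= min_interval))
      acc <- c(acc, i)
  }
  acc <- sort(acc)
  out <- data.frame(index = acc, time = times[acc], amplitude = x[acc],
                    baseline = if (is.null(baseline)) NA_real_
                               else baseline[acc])
  class(out) <- c("peak_list", "data.frame")
  out
}

# Topographic prominence of the local maximum at index i: on each side walk
# out to the nearest strictly-higher sample (or the series end) and take the
# minimum in between; prominence is height above the higher of the two minima.
peak_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  left <- if (i == 1L) h else {
    j <- i - 1L
    lo <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lo) lo <- x[j]
      j <- j - 1L
    }
    lo
  }
  right <- if (i == n) h else {
    j <- i + 1L
    lo <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < lo) lo <- x[j]
      j <- j + 1L
    }
    lo
  }
  h - max(left, right)
}

#' First and last detected beat peaks
#'
#' @param peaks a \code{peak_list} from [find_sweep_peaks()].
#' @return A list with elements \code{first} and \code{last} (one-row data
#'   frames) and \code{degenerate}, \code{TRUE} when only a single peak was
#'   found (both entries are then that peak).
#' @export
first_last_peaks <- function(peaks) {
  if (!nrow(peaks)) stop("no peaks detected")
  list(first = peaks[1L, , drop = FALSE],
       last = peaks[nrow(peaks), , drop = FALSE],
       degenerate = nrow(peaks) == 1L)
}

# Robust estimate of the post-smoothing noise SD: MAD of the detrended
# series' first differences (white noise dominates them; steep beat slopes
# are a minority of samples at 500 Hz), divided by sqrt(k) for the k-point
# moving-average smoother.
smoothed_noise_sd <- function(detrended, smoothed) {
  d <- diff(as.numeric(detrended))
  if (!length(d)) return(0)
  sigma_raw <- 1.4826 * median(abs(d - median(d))) / sqrt(2)
  k <- attr(smoothed, "k") %||% 1L
  sigma_raw / sqrt(k)
}

#' Segment a constant-pressure recording into beats
#'
#' Detects qualifying beat peaks in the detrended, noise-smoothed recording,
#' places beat feet at the smoothed minimum between successive peaks, and
#' returns one beat per (preceding foot, peak) pair. The partial beats
#' before the first detected peak and after the last one are dropped.
#' Indices locate features on the smoothed series but refer to the original
#' samples, so amplitudes can be read from the raw recording.
#'
#' @param rec a \code{step_recording} (see [run_existing_protocol()]).
#' @param min_beat_interval minimum inter-peak interval, s.
#' @param min_prominence minimum peak prominence, mmHg.
#' @param smooth_window noise-smoothing window, s; see [smooth_signal()].
#' @return Data frame with columns \code{foot_index}, \code{peak_index}.
#' @export
segment_beats <- function(rec, min_beat_interval = 0.33, min_prominence = 1,
                          smooth_window = 0.04) {
  stopifnot(inherits(rec, "step_recording"))
  x <- rec$samples
  tms <- rec$times
  if (length(x) < 3 / min_beat_interval)
    stop("insufficient beats: recording shorter than 3 expected beats")
  det <- detrend_sweep(x, tms)
  sm <- smooth_signal(as.numeric(det), tms, smooth_window)
  thr <- min_prominence + 4 * smoothed_noise_sd(det, sm)
  pk <- find_sweep_peaks(sm, tms, min_prominence = thr,
                         min_interval = min_beat_interval)
  if (nrow(pk) < 3L) stop("insufficient beats")
  idx <- pk$index
  # feet on the lightly smoothed recording itself: between two peaks the
  # baseline is constant to within residual drift, and the raw valley is not
  # displaced by the detrender's periodic leakage
  sm_raw <- smooth_signal(x, tms, smooth_window)
  feet <- vapply(seq_len(length(idx) - 1L), function(k) {
    span <- idx[k]:idx[k + 1L]
    span[which.min(sm_raw[span])]
  }, integer(1))
  data.frame(foot_index = feet, peak_index = idx[-1L])
}

#' Per-step pulse pressure
#'
#' The pulse pressure of a 10-s step recording: the mean over complete beats
#' of (peak sample - preceding foot sample). Peak and foot positions come
#' from the smoothed series, but the amplitudes are read from the raw
#' samples at those positions, so the estimate is unbiased under noise and
#' unattenuated without it. Using per-beat amplitudes rather than the
#' window's max-minus-min makes the estimate robust to residual drift, and
#' taking sample differences makes it invariant to constant offsets.
#'
#' @inheritParams segment_beats
#' @return Pulse pressure in mmHg.
#' @export
pulse_pressure <- function(rec, min_beat_interval = 0.33, min_prominence = 1,
                           smooth_window = 0.04) {
  beats <- segment_beats(rec, min_beat_interval, min_prominence,
                         smooth_window)
  mean(rec$samples[beats$peak_index] - rec$samples[beats$foot_index])
}
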