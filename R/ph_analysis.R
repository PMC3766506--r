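#' P-H curve (pulse pressure over hold-down pressure)
#'
#' A natural cubic spline through the five (APP, pulse pressure) points of a
#' completed acquisition. The curve is the object on which the coefficient of
#' floating and sinking pulse is defined.
#'
#' @param app actual applied pressures, mmHg, strictly increasing.
#' @param y pulse pressures at those steps, mmHg.
#' @param grid_step evaluation grid resolution for the argmax search, mmHg.
#' @return An object of class \code{ph_curve}.
#' @export
ph_curve <- function(app, y, grid_step = 0.1) {
  if (length(app) != length(y)) stop("app and y lengths differ")
  if (length(app) < 3) stop("need at least 3 steps")
  if (anyDuplicated(app)) stop("duplicate APPs")
  if (any(diff(app) <= 0)) stop("app must be strictly increasing")
  fun <- splinefun(app, y, method = "natural")
  structure(list(app = app, y = y, fun = fun, grid_step = grid_step),
            class = "ph_curve")
}

#' Build the P-H curve from step recordings
#'
#' Computes each step's pulse pressure with [pulse_pressure()] and fits the
#' natural spline through the (APP, Y) points.
#'
#' @param recordings list of \code{step_recording}s (one acquisition's steps).
#' @param min_beat_interval,min_prominence passed to [pulse_pressure()].
#' @param grid_step see [ph_curve()].
#' @return A \code{ph_curve}.
#' @export
build_ph_curve <- function(recordings, min_beat_interval = 0.33,
                           min_prominence = 1, grid_step = 0.1) {
  app <- vapply(recordings, `[[`, numeric(1), "app")
  y <- vapply(recordings, pulse_pressure, numeric(1),
              min_beat_interval = min_beat_interval,
              min_prominence = min_prominence)
  ord <- order(app)
  ph_curve(app[ord], y[ord], grid_step = grid_step)
}

#' @export
print.ph_curve <- function(x, ...) {
  cat("<ph_curve>\n")
  print(data.frame(app_mmHg = round(x$app, 2), y_mmHg = round(x$y, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @param object a \code{ph_curve}.
#' @param newdata pressures (mmHg) at which to evaluate the spline; defaults
#'   to the knots.
#' @param ... unused.
#' @rdname ph_curve
#' @export
predict.ph_curve <- function(object, newdata = object$app, ...) {
  object$fun(newdata)
}

#' @param x a \code{ph_curve}.
#' @rdname ph_curve
#' @export
plot.ph_curve <- function(x, ...) {
  g <- seq(min(x$app), max(x$app), length.out = 200)
  plot(g, x$fun(g), type = "l", xlab = "hold-down pressure (mmHg)",
       ylab = "pulse pressure (mmHg)", ...)
  points(x$app, x$y, pch = 19)
  invisible(x)
}

#' Pressure of maximum pulse pressure
#'
#' The argmax of the interpolated P-H curve, evaluated on a regular grid
#' (default 0.1 mmHg) over the measured pressure range; ties resolve to the
#' lowest pressure.
#'
#' @param curve a [ph_curve()].
#' @return The pressure X in mmHg.
#' @export
find_x <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  lo <- min(curve$app); hi <- max(curve$app)
  g <- seq(lo, hi, by = curve$grid_step)
  if (g[length(g)] < hi) g <- c(g, hi)
  g[which.max(curve$fun(g))]
}

#' Coefficient of floating and sinking pulse (CFS)
#'
#' The position of the P-H curve maximum within the applied pressure range,
#' scaled to 0--10:
#' \deqn{CFS = 10 (X - X_{min}) / (X_{max} - X_{min})}
#' where \eqn{X_{min}} and \eqn{X_{max}} are the applied pressures of the
#' first and last steps and \eqn{X} the pressure of maximum pulse pressure.
#' Low values indicate a floating (shallow) pulse, high values a sinking
#' (deep) pulse.
#'
#' @param x_min,x_max pressure range endpoints, mmHg, \code{x_min < x_max}.
#' @param x pressure of maximum pulse pressure, in \code{[x_min, x_max]}.
#' @return CFS, dimensionless in \code{[0, 10]}.
#' @export
cfs <- function(x_min, x_max, x) {
  if (x_max <= x_min) stop("degenerate range: x_max must exceed x_min")
  if (x < x_min || x > x_max) stop("x must lie in [x_min, x_max]")
  10 * (x - x_min) / (x_max - x_min)
}

#' Floating/sinking classification
#'
#' CFS below 5 is a floating pulse; 5 or above is sinking. The boundary and
#' its orientation reproduce all 40 reference-cohort labels (values 4.998414
#' and 5.031552 fall on opposite sides).
#'
#' @param cfs_value CFS in \code{[0, 10]}.
#' @return \code{"floating"} or \code{"sinking"}.
#' @export
classify_floating_sinking <- function(cfs_value) {
  if (any(cfs_value < 0 | cfs_value > 10))
    stop("cfs_value out of [0, 10]")
  ifelse(cfs_value < 5, "floating", "sinking")
}

#' Weak-minus-strong pulse pressure index (new CFS)
#'
#' The mean pulse pressure of the two lightest steps (weak pressure) minus
#' the mean of the two heaviest (strong pressure), in mmHg. Positive values
#' are floating-like. Not used for classification: that distinction needs all
#' three palpation positions measured, and only one is.
#'
#' @param y pulse pressures at the 5 steps, mmHg, non-negative.
#' @return An object of class \code{new_cfs} with fields \code{weak},
#'   \code{strong}, \code{new_cfs}.
#' @export
new_cfs <- function(y) {
  if (length(y) != 5L) stop("y must have exactly 5 pulse pressures")
  if (any(y < 0)) stop("pulse pressures must be non-negative")
  weak <- (y[1] + y[2]) / 2
  strong <- (y[4] + y[5]) / 2
  structure(list(weak = weak, strong = strong, new_cfs = weak - strong),
            class = "new_cfs")
}

#' @export
print.new_cfs <- function(x, ...) {
  cat(sprintf("<new_cfs> weak %.3f - strong %.3f = %.3f mmHg\n",
              x$weak, x$strong, x$new_cfs))
  invisible(x)
}

#' Full per-subject analysis of one acquisition
#'
#' Computes per-step pulse pressures, the P-H spline, X, CFS, the
#' floating/sinking label, the weak-minus-strong index and the motor moving
#' distance. A step whose recording contains no detectable beats (pulse below
#' the detector floor, e.g. a fixed-range step beyond the subject's
#' perceptible range) contributes a pulse pressure of 0 when
#' \code{on_missing_pulse = "zero"} (the default), or raises an error when
#' \code{"error"}.
#'
#' @param result an \code{acquisition_result}.
#' @param motor a [motor_config()].
#' @param proto a [protocol_config()].
#' @param on_missing_pulse \code{"zero"} or \code{"error"}.
#' @return An object of class \code{pulse_analysis}.
#' @export
analyze_acquisition <- function(result, motor = motor_config(),
                                proto = protocol_config(),
                                on_missing_pulse = c("zero", "error")) {
  stopifnot(inherits(result, "acquisition_result"))
  on_missing_pulse <- match.arg(on_missing_pulse)
  app <- vapply(result$recordings, `[[`, numeric(1), "app")
  y <- vapply(result$recordings, function(r) {
    if (on_missing_pulse == "error")
      return(pulse_pressure(r, proto$min_beat_interval,
                            proto$min_peak_prominence))
    tryCatch(pulse_pressure(r, proto$min_beat_interval,
                            proto$min_peak_prominence),
             error = function(e) 0)
  }, numeric(1))
  ord <- order(app)
  curve <- ph_curve(app[ord], y[ord])
  x <- find_x(curve)
  x_min <- min(app); x_max <- max(app)
  cfs_value <- cfs(x_min, x_max, x)
  structure(list(subject_id = result$subject_id, method = result$method,
                 app = app[ord], y = y[ord], curve = curve,
                 x_min = x_min, x_max = x_max, x = x, cfs = cfs_value,
                 label = classify_floating_sinking(cfs_value),
                 new_cfs = new_cfs(y[ord])$new_cfs,
                 moving_distance_mm = moving_distance(result, motor)),
            class = "pulse_analysis")
}

#' @export
print.pulse_analysis <- function(x, ...) {
  cat(sprintf("<pulse_analysis %s, %s method>\n", x$subject_id, x$method))
  cat(sprintf("  APP  : %s mmHg\n", paste(sprintf("%.1f", x$app),
                                          collapse = ", ")))
  cat(sprintf("  Y    : %s mmHg\n", paste(sprintf("%.2f", x$y),
                                          collapse = ", ")))
  cat(sprintf("  X = %.1f mmHg in [%.1f, %.1f]  ->  CFS %.3f (%s)\n",
              x$x, x$x_min, x$x_max, x$cfs, x$label))
  cat(sprintf("  new CFS %.3f mmHg, moving distance %.3f mm\n",
              x$new_cfs, x$moving_distance_mm))
  invisible(x)
}
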