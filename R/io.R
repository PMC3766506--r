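# File formats: cohort JSON, per-step recording CSVs with a JSON sidecar,
# sweep CSV, per-subject analysis JSON. CSVs are comma-separated, '.' decimal,
# header row, UTF-8, no index column; times in seconds from recording start,
# pressures in mmHg, motor positions in integer pulses.

profile_to_list <- function(p) {
  list(subject_id = p$subject_id, heart_rate = p$heart_rate,
       p_first = p$p_first, p_peak = p$p_peak, p_last = p$p_last,
       a_max = p$a_max, a_thresh = p$a_thresh,
       contact_depth = p$contact_depth, stiffness = p$stiffness,
       gamma = p$gamma, noise_sd = p$noise_sd, bmi = p$bmi,
       beat = list(percussion_center = p$beat$pc,
                   percussion_width = p$beat$pw,
                   dicrotic_center = p$beat$dc,
                   dicrotic_width = p$beat$dw,
                   dicrotic_weight = p$beat$dweight))
}

profile_from_list <- function(l) {
  subject_profile(subject_id = l$subject_id, heart_rate = l$heart_rate,
                  p_first = l$p_first, p_peak = l$p_peak, p_last = l$p_last,
                  a_max = l$a_max, a_thresh = l$a_thresh,
                  contact_depth = l$contact_depth, stiffness = l$stiffness,
                  gamma = l$gamma, noise_sd = l$noise_sd, bmi = l$bmi,
                  beat = beat_shape(
                    percussion_center = l$beat$percussion_center,
                    percussion_width = l$beat$percussion_width,
                    dicrotic_center = l$beat$dicrotic_center,
                    dicrotic_width = l$beat$dicrotic_width,
                    dicrotic_weight = l$beat$dicrotic_weight))
}

#' Write / read a cohort file
#'
#' Cohort files are JSON with the generating seed recorded alongside the
#' subject profiles.
#'
#' @param cohort list of [subject_profile()]s.
#' @param path output path.
#' @param seed the seed the cohort was generated with (recorded in the file).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NA_integer_) {
  obj <- list(seed = seed, n = length(cohort),
              subjects = lapply(cohort, profile_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cohort <- lapply(obj$subjects, profile_from_list)
  attr(cohort, "seed") <- obj$seed
  cohort
}

# md5 of an object's canonical JSON (used to stamp outputs with their config)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

config_to_list <- function(motor, proto) {
  list(motor = unclass(motor), protocol = unclass(proto))
}

#' Write an acquisition to disk
#'
#' One CSV per step (\code{time_s, pressure_mmHg}), a sweep CSV for adaptive
#' runs (\code{time_s, pressure_mmHg, motor_position_pulses, phase}), and a
#' JSON sidecar holding the method, subject, seed, configuration (with its
#' hash) and per-step target/APP/motor position.
#'
#' @param result an \code{acquisition_result}.
#' @param dir output directory (created if needed).
#' @param motor,proto the configurations the run used.
#' @return Path of the JSON sidecar, invisibly.
#' @export
write_acquisition <- function(result, dir, motor = motor_config(),
                              proto = protocol_config()) {
  stopifnot(inherits(result, "acquisition_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s", result$subject_id, result$method)
  steps <- lapply(result$recordings, function(r) {
    f <- sprintf("%s_step%d.csv", stem, r$step_index)
    write.csv(data.frame(time_s = r$times - r$times[1],
                         pressure_mmHg = r$samples),
              file.path(dir, f), row.names = FALSE)
    list(step_index = r$step_index, target_pressure = r$target_pressure,
         app = r$app, motor_position = r$motor_position,
         within_tolerance = r$within_tolerance, file = f)
  })
  sweep_file <- NULL
  if (!is.null(result$sweep)) {
    sweep_file <- sprintf("%s_sweep.csv", stem)
    write.csv(as.data.frame(result$sweep), file.path(dir, sweep_file),
              row.names = FALSE)
  }
  cfg <- config_to_list(motor, proto)
  sidecar <- list(method = result$method, subject_id = result$subject_id,
                  seed = result$seed, partial = result$partial,
                  config = cfg, config_hash = config_hash(cfg),
                  steps = steps, sweep_file = sweep_file)
  out <- file.path(dir, sprintf("%s.json", stem))
  jsonlite::write_json(sidecar, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Read an acquisition written by [write_acquisition()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return An \code{acquisition_result}.
#' @export
read_acquisition <- function(sidecar) {
  obj <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  dir <- dirname(sidecar)
  fs <- obj$config$motor$sampling_rate
  recs <- lapply(obj$steps, function(s) {
    f <- file.path(dir, s$file)
    d <- read.csv(f)
    if (!all(c("time_s", "pressure_mmHg") %in% names(d)))
      stop(sprintf("corrupt recording file: %s", f))
    step_recording(s$step_index, s$target_pressure, s$app, s$motor_position,
                   d$pressure_mmHg, d$time_s, fs, isTRUE(s$within_tolerance))
  })
  sweep <- NULL
  if (!is.null(obj$sweep_file)) {
    sweep <- read.csv(file.path(dir, obj$sweep_file))
    class(sweep) <- c("sweep_trace", "data.frame")
  }
  acquisition_result(obj$method, obj$subject_id, recs, sweep = sweep,
                     partial = isTRUE(obj$partial),
                     seed = obj$seed %||% NA_integer_)
}

#' Write a per-subject analysis report
#'
#' @param analysis a \code{pulse_analysis}.
#' @param path output JSON path.
#' @param seed,config_hash provenance stamps copied into the report.
#' @return \code{path}, invisibly.
#' @export
write_analysis <- function(analysis, path, seed = NA_integer_,
                           config_hash = NA_character_) {
  stopifnot(inherits(analysis, "pulse_analysis"))
  obj <- list(subject_id = analysis$subject_id, method = analysis$method,
              seed = seed, config_hash = config_hash,
              x_min = analysis$x_min, x_max = analysis$x_max,
              x = analysis$x, cfs = analysis$cfs, label = analysis$label,
              new_cfs = analysis$new_cfs, app = analysis$app, y = analysis$y,
              moving_distance_mm = analysis$moving_distance_mm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
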