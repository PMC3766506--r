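# Reference cohort fixture: 20 subjects measured with both protocols
# (BMI, step1-step5 moving distance, CFS, floating/sinking label, new CFS).
REFERENCE_COHORT_MD5 <- "99de29a1925b68aeca4035acbc1d87ad"

# Published summary values the reference cohort reproduces.
REFERENCE_SUMMARY <- list(
  move_mean_existing = 3.375, move_sd_existing = 0.994,
  move_mean_proposed = 4.089, move_sd_proposed = 1.183,
  cfs_pearson_r = 0.321, paired_t_p_max = 0.003,
  discordant_count = 4, discordant_subjects = c(4L, 5L, 8L, 15L),
  overweight_count = 4)

#' Load the packaged reference cohort
#'
#' Twenty adult subjects measured with both the fixed-range and the adaptive
#' protocol: BMI, step1-to-step5 motor moving distance, CFS, floating/sinking
#' label and the weak-minus-strong index for each method. The file's checksum
#' is verified before loading.
#'
#' @param path path to the CSV; defaults to the packaged copy.
#' @return A 20-row data frame of class \code{table1}.
#' @export
load_table1 <- function(path = system.file("extdata", "reference_cohort.csv",
                                           package = "pulsedepth")) {
  if (!nzchar(path) || !file.exists(path))
    stop("reference cohort fixture not found")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, REFERENCE_COHORT_MD5))
    stop("reference cohort checksum mismatch; refusing to load")
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "bmi", "move_existing", "move_proposed",
            "cfs_existing", "cfs_proposed", "label_existing",
            "label_proposed", "newcfs_existing", "newcfs_proposed")
  if (!all(need %in% names(d))) stop("reference cohort has missing columns")
  if (nrow(d) != 20L) stop("reference cohort must have exactly 20 rows")
  class(d) <- c("table1", "data.frame")
  d
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length >= 2.
#' @return Named vector \code{c(mean =, sd =)}; the SD uses the n-1
#'   denominator.
#' @export
mean_sd <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- sum(values) / n
  c(mean = m, sd = sqrt(sum((values - m)^2) / (n - 1)))
}

#' Paired t-test
#'
#' Two-sided paired t-test on \code{d = b - a}:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with \eqn{df = n - 1}; the p-value is
#' computed through the regularized incomplete beta function,
#' \eqn{p = I_{df/(df+t^2)}(df/2, 1/2)}.
#'
#' @param a,b paired samples of equal length, n >= 2.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("mismatched lengths")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- b - a
  s <- mean_sd(d)[["sd"]]
  if (s == 0) stop("zero variance of differences")
  t <- (sum(d) / n) / (s / sqrt(n))
  df <- n - 1
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

#' Pearson product-moment correlation
#'
#' @param a,b numeric vectors of equal length, n >= 3, non-degenerate.
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("mismatched lengths")
  if (length(a) < 3) stop("need at least 3 pairs")
  ac <- a - mean(a); bc <- b - mean(b)
  va <- sum(ac^2); vb <- sum(bc^2)
  if (va == 0 || vb == 0) stop("degenerate variance")
  sum(ac * bc) / sqrt(va * vb)
}

#' Subjects whose floating/sinking labels disagree between methods
#'
#' @param rows a \code{table1} data frame.
#' @return List with \code{count} and \code{subjects} (ids).
#' @export
discordance <- function(rows) {
  differ <- tolower(rows$label_existing) != tolower(rows$label_proposed)
  list(count = sum(differ), subjects = rows$subject[differ])
}

#' Count overweight subjects
#'
#' @param rows a \code{table1} data frame.
#' @param cutoff BMI cutoff, kg/m^2 (25 = overweight).
#' @return Count of subjects with \code{bmi >= cutoff}.
#' @export
overweight_count <- function(rows, cutoff = 25) {
  sum(rows$bmi >= cutoff)
}

#' Reproduce the reference cohort's summary statistics
#'
#' Recomputes from the packaged fixture: per-method mean/SD of moving
#' distance, the Pearson correlation between the two CFS columns, the paired
#' t-test on moving distance, the discordant floating/sinking subjects and
#' the overweight count, each compared against the published value.
#'
#' @param rows a \code{table1} data frame (defaults to the packaged copy).
#' @return Data frame with columns \code{check}, \code{computed},
#'   \code{expected}, \code{pass}.
#' @export
reproduce_table1 <- function(rows = load_table1()) {
  ms_e <- mean_sd(rows$move_existing)
  ms_p <- mean_sd(rows$move_proposed)
  r <- pearson_r(rows$cfs_existing, rows$cfs_proposed)
  tt <- paired_t_test(rows$move_existing, rows$move_proposed)
  disc <- discordance(rows)
  ow <- overweight_count(rows)
  ref <- REFERENCE_SUMMARY
  chk <- function(check, computed, expected, pass)
    data.frame(check = check, computed = computed, expected = expected,
               pass = pass)
  out <- rbind(
    chk("move mean existing (mm)", ms_e[["mean"]], ref$move_mean_existing,
        round(ms_e[["mean"]], 3) == ref$move_mean_existing),
    chk("move sd existing (mm)", ms_e[["sd"]], ref$move_sd_existing,
        abs(ms_e[["sd"]] - ref$move_sd_existing) < 1e-3),
    chk("move mean proposed (mm)", ms_p[["mean"]], ref$move_mean_proposed,
        round(ms_p[["mean"]], 3) == ref$move_mean_proposed),
    chk("move sd proposed (mm)", ms_p[["sd"]], ref$move_sd_proposed,
        abs(ms_p[["sd"]] - ref$move_sd_proposed) < 1e-3),
    chk("CFS Pearson r", r, ref$cfs_pearson_r,
        round(r, 3) == ref$cfs_pearson_r),
    chk("paired t-test p <=", tt$p, ref$paired_t_p_max,
        tt$p <= ref$paired_t_p_max),
    chk("discordant subjects", disc$count, ref$discordant_count,
        disc$count == ref$discordant_count &&
          identical(sort(disc$subjects), ref$discordant_subjects)))
  out <- rbind(out, chk("overweight subjects (BMI >= 25)", ow,
                        ref$overweight_count, ow == ref$overweight_count))
  class(out) <- c("table1_report", "data.frame")
  out
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Reference cohort reproduction\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-32s computed %10.6f  expected %8.3f  [%s]\n",
                x$check[i], x$computed[i], x$expected[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  invisible(x)
}

#' End-to-end method comparison on a synthetic cohort
#'
#' Generates a cohort, runs both protocols on every subject, analyses each
#' acquisition and assembles the method-comparison statistics: per-method
#' mean/SD of moving distance, the paired t-test on moving distance, the
#' Pearson correlation between the two CFS columns, discordant subjects and
#' the overweight count.
#'
#' @param n cohort size, >= 3.
#' @param seed integer seed; the whole pipeline is deterministic given it.
#' @param motor a [motor_config()].
#' @param proto a [protocol_config()].
#' @param bmi_range,config passed to [make_cohort()].
#' @return An object of class \code{comparison_report}; its \code{subjects}
#'   element holds the per-subject table.
#' @export
simulate_method_comparison <- function(n, seed = 1L, motor = motor_config(),
                                       proto = protocol_config(),
                                       bmi_range = c(18.5, 30.5),
                                       config = cohort_config()) {
  if (n < 3) stop("need n >= 3")
  cohort <- make_cohort(n, seed = seed, bmi_range = bmi_range,
                        config = config)
  rows <- lapply(seq_along(cohort), function(i) {
    prof <- cohort[[i]]
    sub_seed <- (seed + 101L * i) %% .Machine$integer.max
    ex <- analyze_acquisition(
      run_existing_protocol(prof, motor, proto, seed = sub_seed),
      motor, proto)
    pr <- analyze_acquisition(
      run_proposed_protocol(prof, motor, proto, seed = sub_seed + 1L),
      motor, proto)
    data.frame(subject = i, bmi = prof$bmi,
               move_existing = ex$moving_distance_mm,
               move_proposed = pr$moving_distance_mm,
               cfs_existing = ex$cfs, cfs_proposed = pr$cfs,
               label_existing = ex$label, label_proposed = pr$label,
               newcfs_existing = ex$new_cfs, newcfs_proposed = pr$new_cfs)
  })
  subjects <- do.call(rbind, rows)
  ms_e <- mean_sd(subjects$move_existing)
  ms_p <- mean_sd(subjects$move_proposed)
  tt <- paired_t_test(subjects$move_existing, subjects$move_proposed)
  r <- pearson_r(subjects$cfs_existing, subjects$cfs_proposed)
  disc <- discordance(subjects)
  structure(list(n = n, seed = seed, subjects = subjects,
                 move_existing = ms_e, move_proposed = ms_p,
                 paired_t = tt, cfs_pearson_r = r,
                 discordant = disc,
                 overweight_count = overweight_count(subjects)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report, n = %d, seed = %d>\n", x$n, x$seed))
  cat(sprintf("  moving distance existing : %.3f +/- %.3f mm\n",
              x$move_existing[["mean"]], x$move_existing[["sd"]]))
  cat(sprintf("  moving distance proposed : %.3f +/- %.3f mm\n",
              x$move_proposed[["mean"]], x$move_proposed[["sd"]]))
  cat(sprintf("  paired t = %.3f (df %d), p = %.4g\n",
              x$paired_t$t, x$paired_t$df, x$paired_t$p))
  cat(sprintf("  CFS Pearson r = %.3f\n", x$cfs_pearson_r))
  cat(sprintf("  discordant floating/sinking: %d (%s)\n",
              x$discordant$count,
              paste(x$discordant$subjects, collapse = ", ")))
  cat(sprintf("  overweight subjects: %d\n", x$overweight_count))
  invisible(x)
}
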