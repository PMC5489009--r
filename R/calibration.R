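#' Calibrate the metabolic rate against a thermal sensation vote
#'
#' Inverts the PMV model per respondent: finds the metabolic rate M for
#' which PMV(M) equals the respondent's thermal sensation vote (TSV),
#' holding the environment and clothing fixed. PMV is strictly increasing
#' in M over the search interval for environments in the study range, so
#' the root is unique and is bracketed by bisection (deterministic, no
#' random initialisation). Votes that cannot be reached within `bounds`
#' return the nearest bound with `bound_hit` set; nothing throws
#' mid-cohort.
#'
#' All arguments are vectorised over respondents.
#'
#' @param tsv Thermal sensation vote(s) on the 7-point scale, treated as
#'   a continuous target in \[-3, 3\].
#' @param env A [thermal_environment()] (one row, or one per respondent).
#' @param clothing_clo Clothing insulation in clo per respondent.
#' @param bounds Search interval for M in W/m2, default `c(40, 250)`
#'   (generously covers the observed 70-150 W/m2 bulk).
#' @param tol Residual tolerance on |TSV - PMV(M)| for the `converged`
#'   flag, default 1e-5.
#' @param n_iter Number of bisection steps (each halves the interval).
#' @return A data frame of class `calibration_result` with columns
#'   `met_rate_wm2`, `met_units`, `residual`, `converged`,
#'   `bound_hit` (`"none"|"lower"|"upper"`) and `iterations`.
#' @examples
#' env <- thermal_environment(21, 21, 0.5, 0.1)
#' truth <- pmv_engine(21, 21, 0.5, 0.1, met = 87, clo = 0.9)
#' calibrate_met_rate(truth, env, clothing_clo = 0.9)
#' @export
calibrate_met_rate <- function(tsv, env, clothing_clo,
                               bounds = c(40, 250), tol = 1e-5,
                               n_iter = 60L) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  n <- max(length(tsv), nrow(env), length(clothing_clo))
  tsv <- rep_len(as.numeric(tsv), n)
  ta <- rep_len(env$air_temp, n)
  tr <- rep_len(env$radiant_temp, n)
  rh <- rep_len(env$rel_humidity, n)
  v  <- rep_len(env$air_speed, n)
  clo <- rep_len(as.numeric(clothing_clo), n)

  f <- function(m) pmv_engine(ta, tr, rh, v, met = m, clo = clo) - tsv

  lo <- rep(bounds[1], n)
  hi <- rep(bounds[2], n)
  flo <- f(lo)
  fhi <- f(hi)
  bound_hit <- rep("none", n)
  bound_hit[flo > 0] <- "lower"   # even the minimum M predicts too warm
  bound_hit[fhi < 0] <- "upper"   # even the maximum M predicts too cool

  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    up <- fm <= 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  m_est <- (lo + hi) / 2
  m_est[bound_hit == "lower"] <- bounds[1]
  m_est[bound_hit == "upper"] <- bounds[2]

  residual <- abs(f(m_est))
  out <- data.frame(
    met_rate_wm2 = m_est,
    met_units = wm2_to_met(m_est),
    residual = residual,
    converged = residual < tol & bound_hit == "none",
    bound_hit = bound_hit,
    iterations = n_iter
  )
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' Calibrate a whole survey cohort
#'
#' Applies [calibrate_met_rate()] to every filtered survey record, using
#' the daily mean indoor environment of each respondent's survey day
#' (day-level modelling; individual timestamps are not matched to
#' sub-daily climate). The summary reports the median (not the mean) of
#' the calibrated rates, which is robust to the extreme values the exact
#' inversion inevitably produces, and counts estimates outside the
#' plausible 70-150 W/m2 bulk.
#'
#' @param records Filtered survey records: a data frame with at least
#'   `respondent_id`, `survey_day`, `tsv`, `clothing_clo`.
#' @param day_env Per-day environment: a data frame with `survey_day`,
#'   `air_temp`, `radiant_temp`, `rel_humidity`, `air_speed` (see
#'   [daily_indoor_means()]).
#' @inheritParams calibrate_met_rate
#' @return A list of class `met_calibration` with elements `results`
#'   (per-respondent data frame) and `summary` (list with `n`,
#'   `median_wm2`, `median_met`, `n_converged`, `n_bound_hit`,
#'   `n_extreme_low`, `n_extreme_high`).
#' @export
calibrate_cohort <- function(records, day_env, bounds = c(40, 250),
                             tol = 1e-5) {
  if (nrow(records) == 0) stop("empty cohort")
  idx <- match(as.character(records$survey_day),
               as.character(day_env$survey_day))
  if (anyNA(idx))
    stop("no indoor climate for survey day(s): ",
         paste(unique(records$survey_day[is.na(idx)]), collapse = ", "))
  env <- thermal_environment(
    day_env$air_temp[idx], day_env$radiant_temp[idx],
    day_env$rel_humidity[idx], day_env$air_speed[idx]
  )
  cal <- calibrate_met_rate(records$tsv, env, records$clothing_clo,
                            bounds = bounds, tol = tol)
  results <- cbind(
    data.frame(respondent_id = records$respondent_id,
               survey_day = records$survey_day),
    cal
  )
  m <- results$met_rate_wm2
  summary <- list(
    n = nrow(results),
    median_wm2 = stats::median(m),
    median_met = wm2_to_met(stats::median(m)),
    n_converged = sum(results$converged),
    n_bound_hit = sum(results$bound_hit != "none"),
    n_extreme_low = sum(m < 70),
    n_extreme_high = sum(m > 150)
  )
  structure(list(results = results, summary = summary),
            class = "met_calibration")
}

#' @export
print.met_calibration <- function(x, ...) {
  s <- x$summary
  cat("Per-respondent metabolic-rate calibration\n")
  cat(sprintf("  respondents: %d (converged %d, at bounds %d)\n",
              s$n, s$n_converged, s$n_bound_hit))
  cat(sprintf("  median: %.1f W/m2 = %.2f Met\n", s$median_wm2, s$median_met))
  cat(sprintf("  outside 70-150 W/m2: %d low, %d high\n",
              s$n_extreme_low, s$n_extreme_high))
  invisible(x)
}

#' Write per-respondent calibration results
#'
#' @param calibration A `met_calibration` object.
#' @param path Output file path (delimited text).
#' @export
write_calibration <- function(calibration, path) {
  write_precise_csv(calibration$results, path)
  invisible(path)
}
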