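#' Run the full thermal-sensation analysis pipeline
#'
#' End-to-end analysis of a survey campaign:
#' \enumerate{
#'   \item filter the records ([filter_samples()]);
#'   \item calibrate each respondent's metabolic rate against their
#'     sensation vote under the daily mean environment
#'     ([calibrate_cohort()]);
#'   \item aggregate to survey days with the PMV at the a-priori
#'     standard metabolic rate (`pmv_std`) and at the cohort's median
#'     calibrated rate (`pmv_met`) ([aggregate_daily()]);
#'   \item evaluate both by identity regression of the actual mean votes
#'     on the predictions ([fit_identity_regression()]);
#'   \item screen the day-level residuals (AMV - PMV_met) against RMOT,
#'     clothing and indoor humidity, fit the affine RMOT extension
#'     (PMV*), then the thermal-preference extension (PMV**), and screen
#'     the post-extension residuals again;
#'   \item compare calibrated metabolic rates between the adult and
#'     elderly age groups per gender ([compare_age_groups()]).
#' }
#'
#' @param survey Survey records data frame (see [read_survey()]).
#' @param indoor Indoor climate series (see [read_indoor_climate()]).
#' @param outdoor Outdoor daily series covering every survey day plus
#'   three lead-in days.
#' @param met_std_met A-priori metabolic rate in Met, default 1.5.
#' @param bounds Calibration search interval in W/m2.
#' @param min_time Minimum visit duration in minutes for the filter.
#' @param screening_threshold Relevance threshold on |r| for the
#'   residual-correlation screen.
#' @return A list of class `comfort_analysis` with elements `records`
#'   (filtered), `exclusions`, `calibration`, `daily`, `fits` (identity
#'   fits for `std`, `met`, `star`, `star_star`), `extension`,
#'   `screening` (`pre` and `post`), and `groups`.
#' @examples
#' camp <- simulate_campaign(synthetic_config(n_days = 8, n_respondents = 240),
#'                           seed = 42)
#' res <- run_comfort_pipeline(camp$survey, camp$indoor, camp$outdoor)
#' res$fits$star
#' @export
run_comfort_pipeline <- function(survey, indoor, outdoor,
                                 met_std_met = 1.5,
                                 bounds = c(40, 250),
                                 min_time = 20,
                                 screening_threshold = 0.3) {
  filt <- filter_samples(survey, min_time = min_time)
  day_env <- daily_indoor_means(indoor)
  cal <- calibrate_cohort(filt, day_env, bounds = bounds)

  daily <- aggregate_daily(filt, indoor, outdoor,
                           met_std_wm2 = met_to_wm2(met_std_met),
                           met_calibrated_wm2 = cal$summary$median_wm2)

  fit_std <- fit_identity_regression(daily$amv, daily$pmv_std)
  fit_met <- fit_identity_regression(daily$amv, daily$pmv_met)

  resid_met <- daily$amv - daily$pmv_met
  candidates <- data.frame(rmot = daily$rmot, clo = daily$mean_clo,
                           rh_indoor = daily$rel_humidity)
  screen_pre <- screen_residual_correlations(resid_met, candidates,
                                             threshold = screening_threshold)

  ext <- fit_rmot_extension(resid_met, daily$rmot)
  daily$pmv_star <- predict_pmv_star(daily$pmv_met, daily$rmot, ext)
  fit_star <- fit_identity_regression(daily$amv, daily$pmv_star)

  resid_star <- daily$amv - daily$pmv_star
  screen_post <- post_extension_screen(resid_star, candidates,
                                       threshold = screening_threshold)

  fit_star_star <- NULL
  if (!all(is.na(daily$mean_preference)) &&
      stats::sd(daily$mean_preference) > 0) {
    ext <- fit_preference_extension(ext, resid_star, daily$mean_preference)
    daily$pmv_star_star <- predict_pmv_star_star(daily$pmv_star,
                                                 daily$mean_preference, ext)
    fit_star_star <- fit_identity_regression(daily$amv, daily$pmv_star_star)
  }

  groups <- compare_age_groups(cal$results$met_rate_wm2, filt$age, filt$gender)

  structure(list(
    records = filt,
    exclusions = exclusion_log(filt),
    calibration = cal,
    daily = daily,
    fits = list(std = fit_std, met = fit_met, star = fit_star,
                star_star = fit_star_star),
    extension = ext,
    screening = list(pre = screen_pre, post = screen_post),
    groups = groups
  ), class = "comfort_analysis")
}

#' @export
print.comfort_analysis <- function(x, ...) {
  cat("Thermal-sensation analysis of", x$calibration$summary$n,
      "respondents over", nrow(x$daily), "survey days\n\n")
  cat(sprintf("Median calibrated metabolic rate: %.1f W/m2 (%.2f Met)\n\n",
              x$calibration$summary$median_wm2,
              x$calibration$summary$median_met))
  cat("AMV ~ PMV   (a-priori Met):   "); print(x$fits$std)
  cat("AMV ~ PMV_met (median Met):   "); print(x$fits$met)
  cat("AMV ~ PMV*  (RMOT-extended):  "); print(x$fits$star)
  if (!is.null(x$fits$star_star)) {
    cat("AMV ~ PMV** (+ preference):   "); print(x$fits$star_star)
  }
  cat("\n"); print(x$extension)
  cat("\n"); print(x$groups)
  invisible(x)
}
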