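#' Filter survey records
#'
#' Drops records with missing required fields, out-of-scale or otherwise
#' erratic values, or a short stay. "Erratic" is operationalised as a
#' vote outside its scale, a negative duration, or a physically
#' implausible clothing level (> `max_clo`). Respondents must have been
#' in the venue at least `min_time` minutes so that their sensation
#' reflects the indoor climate rather than the outdoors.
#'
#' @param records Survey records data frame with columns `tsv`,
#'   `time_in_venue`, `clothing_clo`, `gender`, `age` (others pass
#'   through).
#' @param min_time Minimum time in the venue in minutes, default 20.
#' @param max_clo Maximum plausible clothing insulation in clo, default 3.
#' @return The retained records, with an `exclusions` attribute: a data
#'   frame tallying records dropped per reason (retrievable with
#'   [exclusion_log()]).
#' @examples
#' r <- data.frame(tsv = c(0, 5, NA), time_in_venue = c(30, 40, 50),
#'                 clothing_clo = 1, gender = "female", age = 70)
#' nrow(filter_samples(r))
#' @export
filter_samples <- function(records, min_time = 20, max_clo = 3) {
  required <- c("tsv", "time_in_venue", "clothing_clo", "gender", "age")
  miss_col <- setdiff(required, names(records))
  if (length(miss_col))
    stop("records lack required column(s): ", paste(miss_col, collapse = ", "))

  has_missing <- Reduce(`|`, lapply(records[required], is.na))
  erratic <- !has_missing & (
    records$tsv < -3 | records$tsv > 3 |
      records$time_in_venue < 0 |
      records$clothing_clo < 0 | records$clothing_clo > max_clo |
      (if ("preference" %in% names(records))
        !is.na(records$preference) &
         (records$preference < -2 | records$preference > 2)
       else FALSE)
  )
  short <- !has_missing & !erratic & records$time_in_venue < min_time

  keep <- !(has_missing | erratic | short)
  log <- data.frame(
    reason = c("missing_value", "erratic_value", "short_visit"),
    n = c(sum(has_missing), sum(erratic), sum(short))
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- log
  message(sprintf("filter_samples: kept %d of %d records (%d missing, %d erratic, %d short visits)",
                  nrow(out), nrow(records), log$n[1], log$n[2], log$n[3]))
  out
}

#' @rdname filter_samples
#' @export
exclusion_log <- function(records) attr(records, "exclusions")

#' Transcribe a garment selection to a clo value
#'
#' Sums per-garment insulation values from a garment table to obtain the
#' ensemble clo. The packaged table ([default_garment_table()]) carries
#' ASHRAE-style per-garment values and is a documented stand-in for the
#' survey checklist actually used in any particular campaign.
#'
#' @param garments Character vector of garment codes (may be empty).
#' @param table A data frame with columns `code` and `clo`.
#' @return Ensemble insulation in clo.
#' @examples
#' transcribe_clothing(c("trousers", "shirt_short", "sweater"))
#' @export
transcribe_clothing <- function(garments, table = default_garment_table()) {
  if (length(garments) == 0) return(0)
  idx <- match(garments, table$code)
  if (anyNA(idx))
    stop("unknown garment code(s): ",
         paste(unique(garments[is.na(idx)]), collapse = ", "))
  sum(table$clo[idx])
}

#' @rdname transcribe_clothing
#' @export
default_garment_table <- function() {
  path <- system.file("extdata", "garment_clo.csv", package = "pmvcal",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate survey records to survey days
#'
#' Collapses respondent records and climate series to one row per survey
#' day: the actual mean vote (AMV, the day mean of the TSVs), daily mean
#' clothing and preference, daily mean indoor environment, the running
#' mean outdoor temperature, and the day's PMV evaluated at the daily
#' mean inputs. Two PMV variants are attached: `pmv_std` at the a-priori
#' standard metabolic rate and, when supplied, `pmv_met` at the cohort's
#' median calibrated rate.
#'
#' @param records Filtered survey records.
#' @param indoor Indoor climate series (see [read_indoor_climate()]).
#' @param outdoor Outdoor daily series with `date`, `t_min`, `t_max`,
#'   covering each survey day and the three preceding days.
#' @param met_std_wm2 A-priori metabolic rate in W/m2, default 1.5 Met.
#' @param met_calibrated_wm2 Optional median calibrated metabolic rate in
#'   W/m2 for the `pmv_met` column.
#' @return A data frame of class `daily_aggregate`, one row per survey
#'   day.
#' @export
aggregate_daily <- function(records, indoor, outdoor,
                            met_std_wm2 = met_to_wm2(1.5),
                            met_calibrated_wm2 = NULL) {
  env <- daily_indoor_means(indoor)
  days <- sort(unique(as.Date(records$survey_day)))
  if (!all(days %in% env$survey_day))
    stop("no indoor data for survey day(s): ",
         paste(format(days[!days %in% env$survey_day]), collapse = ", "))
  out <- add_rmot(outdoor)

  rows <- lapply(days, function(d) {
    rec <- records[as.Date(records$survey_day) == d, , drop = FALSE]
    e <- env[env$survey_day == d, , drop = FALSE]
    rmot <- out$rmot[match(d, out$date)]
    if (is.na(rmot))
      stop("cannot compute RMOT for ", format(d),
           ": outdoor series lacks the day or its three-day history")
    data.frame(
      survey_day = d,
      n_respondents = nrow(rec),
      amv = mean(rec$tsv),
      mean_clo = mean(rec$clothing_clo),
      mean_preference = if ("preference" %in% names(rec))
        mean(rec$preference) else NA_real_,
      air_temp = e$air_temp, radiant_temp = e$radiant_temp,
      rel_humidity = e$rel_humidity, air_speed = e$air_speed,
      t_op = e$t_op, rmot = rmot
    )
  })
  daily <- do.call(rbind, rows)
  daily$pmv_std <- pmv_engine(daily$air_temp, daily$radiant_temp,
                              daily$rel_humidity, daily$air_speed,
                              met = met_std_wm2, clo = daily$mean_clo)
  if (!is.null(met_calibrated_wm2))
    daily$pmv_met <- pmv_engine(daily$air_temp, daily$radiant_temp,
                                daily$rel_humidity, daily$air_speed,
                                met = met_calibrated_wm2,
                                clo = daily$mean_clo)
  class(daily) <- c("daily_aggregate", "data.frame")
  daily
}

#' Identity regression of actual on predicted votes
#'
#' Ordinary least squares of the actual mean votes on a predicted-vote
#' series (Actual = a1 Predicted + a0). Perfect prediction corresponds to
#' slope 1, intercept 0 and R-squared 1; a slope above 1 means the model
#' under-predicts the more extreme sensations.
#'
#' @param actual Actual mean votes (one per day).
#' @param predicted Predicted votes (same length, non-constant).
#' @return A list of class `identity_fit`: `slope`, `intercept`,
#'   `r_squared`, `slope_ci95`, `p_value` (slope), `n`, and the
#'   underlying `lm` fit.
#' @examples
#' fit_identity_regression(c(-1, 0, 1, 2), c(-0.5, 0.1, 0.6, 1.1))
#' @export
fit_identity_regression <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (length(actual) < 3) stop("need at least 3 paired points")
  if (stats::sd(predicted) == 0) stop("predictor is constant")
  fit <- stats::lm(actual ~ predicted)
  sm <- summary(fit)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    slope_ci95 = unname(stats::confint(fit, "predicted", level = 0.95)[1, ]),
    p_value = sm$coefficients["predicted", "Pr(>|t|)"],
    n = length(actual),
    fit = fit
  )
  class(out) <- "identity_fit"
  out
}

#' @export
print.identity_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Actual = %.*f Predicted %+.*f   (R2 = %.2f, n = %d)\n",
              digits, x$slope, digits, x$intercept, x$r_squared, x$n))
  cat(sprintf("  slope 95%% CI: %.*f to %.*f, p = %.3g\n",
              digits, x$slope_ci95[1], digits, x$slope_ci95[2], x$p_value))
  invisible(x)
}
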