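#' Configuration for the synthetic survey campaign generator
#'
#' Defines the study conditions the generator emulates: a museum-style
#' campaign of weekly survey days spanning late winter to autumn, a
#' cohort dominated by elderly females, tightly controlled indoor
#' operative temperatures between 19.5 and 24 degrees C at 50 % relative
#' humidity and low air speed, and thermal sensation votes produced by
#' the heat-balance model of each respondent's true metabolic rate plus
#' an affine running-mean-outdoor-temperature (RMOT) effect. The injected
#' RMOT coefficients are the generator's ground truth and what the
#' model-extension stage should recover.
#'
#' @param n_days Number of survey days (weekly), default 35.
#' @param n_respondents Total respondents across the campaign, default
#'   1121 (allocated evenly over days, so at least 30 per day).
#' @param cell_counts Named counts for the four age-gender study cells
#'   (adults 30-40 y, elderly 65-75 y); the remainder of the cohort is
#'   spread over 18-80 y.
#' @param remainder_female_prob Probability that a remainder respondent
#'   is female (the venue population is female-skewed).
#' @param indoor_temp_range Operative temperature range, degrees C.
#' @param rh,rh_jitter Relative humidity level (fraction) and its
#'   day-to-day jitter SD.
#' @param air_speed_range Air speed range, m/s.
#' @param true_beta_rmot,true_intercept Injected affine RMOT effect on
#'   the sensation scale (per degree C, and offset).
#' @param tsv_noise_sd SD of the respondent-level sensation noise.
#' @param clo_base,clo_rmot_slope,clo_noise_sd Clothing model: ensemble
#'   clo at RMOT 0, its decrease per degree C of RMOT (seasonal clothing
#'   adjustment, which deliberately confounds clothing with RMOT), and
#'   respondent-level noise.
#' @param pref_slope,pref_noise_sd Thermal preference model: preference
#'   is a noisy decreasing function of the sensation vote
#'   (warmer-positive coding), rounded to the integer scale -2..2.
#' @param activity_median,activity_sdlog Lognormal activity factor
#'   multiplying each respondent's personal 1-Met heat equivalent to give
#'   the true metabolic rate.
#' @param contaminated_frac Fraction of records given a sub-20-minute
#'   visit, for exercising the filter; default 0.
#' @param round_tsv Round votes to integers (stress test; off by default
#'   so the exact-fit calibration round-trips).
#' @param start_date First survey day (a Wednesday).
#' @param outdoor_noise_sd SD of the AR(1) day-to-day outdoor
#'   temperature noise; 0 gives a pure seasonal sinusoid.
#' @param anthro_height_sd,anthro_weight_sd SDs around the reference
#'   mean height (cm) and weight (kg).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_days = 35,
                             n_respondents = 1121,
                             cell_counts = c(adult_male = 60,
                                             adult_female = 50,
                                             elderly_male = 128,
                                             elderly_female = 224),
                             remainder_female_prob = 0.6,
                             indoor_temp_range = c(19.5, 24),
                             rh = 0.50, rh_jitter = 0.01,
                             air_speed_range = c(0.05, 0.15),
                             true_beta_rmot = -0.024,
                             true_intercept = 0.264,
                             tsv_noise_sd = 0.25,
                             clo_base = 1.25,
                             clo_rmot_slope = 0.025,
                             clo_noise_sd = 0.10,
                             pref_slope = -0.9,
                             pref_noise_sd = 0.4,
                             activity_median = 1.8,
                             activity_sdlog = 0.12,
                             contaminated_frac = 0,
                             round_tsv = FALSE,
                             start_date = as.Date("2015-02-04"),
                             outdoor_noise_sd = 2,
                             anthro_height_sd = 7,
                             anthro_weight_sd = 12) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_days >= 1, cfg$n_respondents >= cfg$n_days,
            diff(cfg$indoor_temp_range) > 0, diff(cfg$air_speed_range) > 0,
            cfg$rh >= 0 && cfg$rh <= 1,
            cfg$contaminated_frac >= 0 && cfg$contaminated_frac < 1,
            sum(cfg$cell_counts) <= cfg$n_respondents)
  cfg$start_date <- as.Date(cfg$start_date)
  class(cfg) <- "synthetic_config"
  cfg
}

survey_days_of <- function(config) config$start_date + 7 * (seq_len(config$n_days) - 1)

#' Generate the outdoor daily temperature series
#'
#' Daily minimum/maximum temperatures for a continuous calendar range
#' covering all survey days plus a three-day lead-in: a seasonal sinusoid
#' (temperate-maritime amplitude) plus AR(1) noise, with a diurnal range
#' around 8 degrees C. No calendar gaps, `t_min <= t_max` by
#' construction.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return An outdoor series data frame `date`, `t_min`, `t_max`.
#' @export
generate_outdoor_series <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  days <- survey_days_of(config)
  dates <- seq(min(days) - 3, max(days), by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- 9 + 8 * sin(2 * pi * (doy - 110) / 365)
  n <- length(dates)
  noise <- if (config$outdoor_noise_sd > 0) {
    as.numeric(stats::filter(stats::rnorm(n, 0, config$outdoor_noise_sd),
                             0.7, method = "recursive"))
  } else rep(0, n)
  t_mean <- seasonal + noise
  half_range <- pmax(0.5, 4 + stats::rnorm(n, 0, 0.2 * config$outdoor_noise_sd))
  data.frame(date = dates,
             t_min = t_mean - half_range,
             t_max = t_mean + half_range)
}

#' Generate the indoor climate series
#'
#' One short block of measurement rows per survey day. The daily
#' operative-temperature setpoint is drawn uniformly over the configured
#' range, independent of the outdoor climate (the campaign deliberately
#' varies the setpoint); relative humidity is held at the configured
#' level with small jitter, air speed stays in the low-speed range.
#'
#' @inheritParams generate_outdoor_series
#' @return An indoor series data frame `survey_day`, `hour`, `air_temp`,
#'   `radiant_temp`, `rel_humidity`, `air_speed`.
#' @export
generate_indoor_series <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  days <- survey_days_of(config)
  rng <- config$indoor_temp_range
  rows <- lapply(seq_along(days), function(i) {
    setpoint <- stats::runif(1, rng[1] + 0.1, rng[2] - 0.1)
    split <- stats::rnorm(1, 0, 0.3)      # air/radiant asymmetry
    hour <- 11:14
    jit <- pmin(pmax(stats::rnorm(4, 0, 0.03), -0.08), 0.08)
    data.frame(
      survey_day = days[i], hour = hour,
      air_temp = setpoint - split / 2 + jit,
      radiant_temp = setpoint + split / 2 + jit,
      rel_humidity = pmin(pmax(config$rh + stats::rnorm(1, 0, config$rh_jitter), 0.3), 0.7),
      air_speed = stats::runif(1, config$air_speed_range[1], config$air_speed_range[2])
    )
  })
  do.call(rbind, rows)
}

# reference mean anthropometrics interpolated in age between the
# adult (35 y) and elderly (70 y) anchors, clamped outside
anthro_means <- function(age, gender) {
  ref <- list(
    male = list(h = c(182.5, 177.3), w = c(83.2, 84.5)),
    female = list(h = c(168.9, 164.9), w = c(69.9, 71.4))
  )
  f <- pmin(pmax((age - 35) / 35, 0), 1)
  h <- ifelse(gender == "male",
              ref$male$h[1] + f * diff(ref$male$h),
              ref$female$h[1] + f * diff(ref$female$h))
  w <- ifelse(gender == "male",
              ref$male$w[1] + f * diff(ref$male$w),
              ref$female$w[1] + f * diff(ref$female$w))
  list(height = h, weight = w)
}

#' Generate the respondent skeleton and ground truth
#'
#' Samples demographics (the four study cells at their configured exact
#' counts, remainder spread over 18-80 y and female-skewed),
#' anthropometrics around the reference means for the respondent's age
#' and gender, visit durations, and each respondent's true metabolic
#' rate: the personal 1-Met heat equivalent from the anthropometrics
#' times a lognormal activity factor. Respondents are allocated evenly
#' over survey days.
#'
#' @inheritParams generate_outdoor_series
#' @return A list with `records` (survey skeleton without votes) and
#'   `truth` (per-respondent `true_met_wm2`, `activity`,
#'   `one_met_equivalent`).
#' @export
generate_respondents <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_respondents
  cc <- config$cell_counts
  n_rem <- n - sum(cc)

  gender <- c(rep("male", cc[["adult_male"]]), rep("female", cc[["adult_female"]]),
              rep("male", cc[["elderly_male"]]), rep("female", cc[["elderly_female"]]))
  age <- c(sample(30:40, cc[["adult_male"]], replace = TRUE),
           sample(30:40, cc[["adult_female"]], replace = TRUE),
           sample(65:75, cc[["elderly_male"]], replace = TRUE),
           sample(65:75, cc[["elderly_female"]], replace = TRUE))
  if (n_rem > 0) {
    # remainder ages avoid the two study cells so the cell counts stay at
    # their configured values; weights lean elderly like the venue
    allowed <- c(18:29, 41:64, 76:80)
    age_rem <- sample(allowed, n_rem, replace = TRUE,
                      prob = ifelse(allowed >= 50, 2.5, 1))
    gender_rem <- ifelse(stats::runif(n_rem) < config$remainder_female_prob,
                         "female", "male")
    gender <- c(gender, gender_rem)
    age <- c(age, age_rem)
  }

  ord <- sample.int(n)            # shuffle before day allocation
  gender <- gender[ord]; age <- age[ord]

  days <- survey_days_of(config)
  day_alloc <- sort(rep_len(seq_len(config$n_days), n))

  mu <- anthro_means(age, gender)
  height <- pmax(140, mu$height + stats::rnorm(n, 0, config$anthro_height_sd))
  weight <- pmax(40, mu$weight + stats::rnorm(n, 0, config$anthro_weight_sd))

  time_in_venue <- 20 + stats::rlnorm(n, meanlog = log(40), sdlog = 0.5)
  n_bad <- round(config$contaminated_frac * n)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    time_in_venue[bad] <- stats::runif(n_bad, 2, 19)
  }

  ome <- one_met_equivalent_wm2(weight, height, age, gender)
  activity <- stats::rlnorm(n, meanlog = log(config$activity_median),
                            sdlog = config$activity_sdlog)

  records <- data.frame(
    respondent_id = seq_len(n),
    survey_day = days[day_alloc],
    gender = gender, age = age,
    height_cm = height, weight_kg = weight,
    time_in_venue = time_in_venue,
    language = sample(c("NL", "EN"), n, replace = TRUE, prob = c(0.8, 0.2))
  )
  truth <- data.frame(
    respondent_id = records$respondent_id,
    one_met_equivalent = ome,
    activity = activity,
    true_met_wm2 = ome * activity
  )
  list(records = records, truth = truth)
}

#' Generate votes and clothing for a respondent skeleton
#'
#' Completes the survey records: clothing follows the seasonal model
#' clo = base - slope x RMOT + noise; the sensation vote is the forward
#' PMV of the respondent's true metabolic rate under the day's mean
#' indoor environment plus the injected affine RMOT effect and Gaussian
#' noise, clamped to the 7-point scale (kept continuous by default);
#' thermal preference is a noisy decreasing function of the vote rounded
#' to -2..2; comfort and acceptability are derived pass-through ordinals.
#'
#' @param records Respondent skeleton from [generate_respondents()].
#' @param indoor Indoor series from [generate_indoor_series()].
#' @param outdoor Outdoor series from [generate_outdoor_series()].
#' @param truth Ground-truth data frame from [generate_respondents()].
#' @inheritParams generate_outdoor_series
#' @return The completed survey records data frame.
#' @export
generate_votes <- function(records, indoor, outdoor, truth,
                           config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  env <- daily_indoor_means(indoor)
  out <- add_rmot(outdoor)
  idx <- match(as.character(records$survey_day), as.character(env$survey_day))
  if (anyNA(idx))
    stop("indoor climate missing for survey day(s): ",
         paste(unique(records$survey_day[is.na(idx)]), collapse = ", "))
  rmot <- out$rmot[match(as.character(records$survey_day),
                         as.character(out$date))]
  if (anyNA(rmot)) stop("outdoor series does not cover all survey days")

  n <- nrow(records)
  clo <- config$clo_base - config$clo_rmot_slope * rmot +
    stats::rnorm(n, 0, config$clo_noise_sd)
  clo <- pmin(pmax(clo, 0.3), 2.5)

  m <- truth$true_met_wm2[match(records$respondent_id, truth$respondent_id)]
  pmv_true <- pmv_engine(env$air_temp[idx], env$radiant_temp[idx],
                         env$rel_humidity[idx], env$air_speed[idx],
                         met = m, clo = clo)
  tsv <- pmv_true + config$true_beta_rmot * rmot + config$true_intercept +
    stats::rnorm(n, 0, config$tsv_noise_sd)
  tsv <- pmin(pmax(tsv, -3), 3)
  if (config$round_tsv) tsv <- round(tsv)

  preference <- round(pmin(pmax(
    config$pref_slope * tsv + stats::rnorm(n, 0, config$pref_noise_sd),
    -2), 2))
  comfort <- round(pmin(pmax(4 - 1.2 * abs(tsv) + stats::rnorm(n, 0, 0.5), 1), 5))
  acceptability <- stats::rbinom(n, 1, stats::plogis(2.5 - 1.5 * abs(tsv)))

  records$clothing_clo <- clo
  records$tsv <- tsv
  records$preference <- preference
  records$comfort <- comfort
  records$acceptability <- acceptability
  records
}

#' Simulate a complete survey campaign
#'
#' Runs the three generator stages under a single seed and returns the
#' campaign with its ground truth. The same seed reproduces the dataset
#' bit-for-bit.
#'
#' @inheritParams generate_outdoor_series
#' @return A list of class `synthetic_campaign` with `survey`, `indoor`,
#'   `outdoor`, `truth`, `config`, `seed`.
#' @examples
#' camp <- simulate_campaign(synthetic_config(n_days = 6, n_respondents = 60),
#'                           seed = 1)
#' nrow(camp$survey)
#' @export
simulate_campaign <- function(config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  outdoor <- generate_outdoor_series(config)
  indoor <- generate_indoor_series(config)
  resp <- generate_respondents(config)
  survey <- generate_votes(resp$records, indoor, outdoor, resp$truth, config)
  structure(list(survey = survey, indoor = indoor, outdoor = outdoor,
                 truth = resp$truth, config = config, seed = seed),
            class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat(sprintf("Synthetic survey campaign: %d respondents over %d survey days\n",
              nrow(x$survey), length(unique(x$survey$survey_day))))
  cat(sprintf("  injected RMOT effect: %+.3f per degC %+.3f\n",
              x$config$true_beta_rmot, x$config$true_intercept))
  invisible(x)
}

#' Write a synthetic campaign to delimited text files
#'
#' Writes `survey.csv`, `indoor_climate.csv`, `outdoor_climate.csv` and
#' the ground-truth sidecar `truth.csv` (which the analysis readers never
#' consume). Numeric columns are written at full precision so re-reading
#' reproduces the objects exactly.
#'
#' @param campaign A `synthetic_campaign`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
emit_dataset <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_survey(campaign$survey, file.path(dir, "survey.csv"))
  ind <- campaign$indoor
  ind$survey_day <- format(ind$survey_day)
  write_precise_csv(ind, file.path(dir, "indoor_climate.csv"))
  outd <- campaign$outdoor
  outd$date <- format(outd$date)
  write_precise_csv(outd, file.path(dir, "outdoor_climate.csv"))
  write_precise_csv(campaign$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
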