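toy_records <- function() {
  data.frame(
    respondent_id = 1:6,
    survey_day = as.Date("2015-03-04"),
    gender = "female", age = 70,
    time_in_venue = c(30, 15, 45, 60, 25, 90),
    tsv = c(0, 1, NA, 5, -1, 2),
    clothing_clo = c(1, 1, 1, 1, 1, 1)
  )
}

test_that("filtering drops missing, erratic and short-visit records", {
  out <- suppressMessages(filter_samples(toy_records()))
  expect_equal(nrow(out), 3)  # 15-min visit, NA tsv, tsv = 5 dropped
  log <- exclusion_log(out)
  expect_equal(log$n[log$reason == "missing_value"], 1)
  expect_equal(log$n[log$reason == "erratic_value"], 1)
  expect_equal(log$n[log$reason == "short_visit"], 1)
})

test_that("filtering keeps all-valid input unchanged and is idempotent", {
  valid <- toy_records()[c(1, 6), ]
  once <- suppressMessages(filter_samples(valid))
  expect_equal(once$respondent_id, valid$respondent_id)
  twice <- suppressMessages(filter_samples(once))
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("clothing transcription sums garment values from the table", {
  expect_equal(transcribe_clothing(character(0)), 0)
  tab <- default_garment_table()
  one <- tab$code[which(tab$clo == 0.25)[1]]
  expect_equal(transcribe_clothing(one), 0.25)
  expect_equal(transcribe_clothing(c("trousers", "shirt_short", "sweater")),
               0.72)
  expect_error(transcribe_clothing("spacesuit"), "spacesuit")
})

test_that("daily aggregation averages votes and inputs per survey day", {
  days <- as.Date("2015-03-04") + c(0, 0, 0, 7)
  records <- data.frame(
    respondent_id = 1:4, survey_day = days,
    gender = "female", age = 70, time_in_venue = 60,
    tsv = c(-1, 0, 1, 0.5), clothing_clo = c(0.8, 1.0, 1.2, 1.0),
    preference = c(1, 0, -1, 0)
  )
  indoor <- data.frame(survey_day = rep(unique(days), each = 2),
                       air_temp = 21, radiant_temp = 21.5,
                       rel_humidity = 0.5, air_speed = 0.1)
  outdoor <- data.frame(date = seq(min(days) - 3, max(days), by = "day"),
                        t_min = 5, t_max = 11)
  agg <- aggregate_daily(records, indoor, outdoor)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$amv, c(0, 0.5))
  expect_equal(agg$n_respondents, c(3, 1))
  expect_equal(agg$mean_clo, c(1, 1))
  expect_equal(agg$rmot, c(8, 8))
  expect_equal(agg$t_op, c(21.25, 21.25))
  expect_true(all(is.finite(agg$pmv_std)))
  # single respondent day: AMV is that vote
  expect_equal(agg$amv[2], records$tsv[4])
})

test_that("aggregation errors when climate is missing", {
  records <- data.frame(respondent_id = 1, survey_day = as.Date("2015-03-04"),
                        tsv = 0, clothing_clo = 1, preference = 0)
  indoor <- data.frame(survey_day = as.Date("2015-03-11"), air_temp = 21,
                       radiant_temp = 21, rel_humidity = 0.5, air_speed = 0.1)
  outdoor <- data.frame(date = as.Date("2015-03-01") + 0:10, t_min = 5, t_max = 11)
  expect_error(aggregate_daily(records, indoor, outdoor), "no indoor data")
})

test_that("AMV is invariant to record order", {
  days <- rep(as.Date("2015-03-04"), 5)
  records <- data.frame(respondent_id = 1:5, survey_day = days,
                        tsv = c(-2, -1, 0, 1, 2), clothing_clo = 1,
                        preference = 0)
  indoor <- data.frame(survey_day = days[1], air_temp = 21, radiant_temp = 21,
                       rel_humidity = 0.5, air_speed = 0.1)
  outdoor <- data.frame(date = days[1] - 3:0, t_min = 5, t_max = 11)
  a <- aggregate_daily(records, indoor, outdoor)
  b <- aggregate_daily(records[sample.int(5), ], indoor, outdoor)
  expect_equal(a$amv, b$amv)
})

test_that("identity regression matches the closed-form OLS oracle", {
  expect_equal(
    suppressWarnings(fit_identity_regression(c(1, 2, 3), c(1, 2, 3)))$slope, 1)
  exact <- suppressWarnings(  # noiseless line: lm warns about perfect fit
    fit_identity_regression(2 * c(0.1, 0.5, 0.9, 1.3) + 1,
                            c(0.1, 0.5, 0.9, 1.3)))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  set.seed(3)
  x <- rnorm(35); y <- 1.6 * x - 0.03 + rnorm(35, 0, 0.2)
  fit <- fit_identity_regression(y, x)
  ora <- oracle_ols(x, y)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-10)
  expect_equal(fit$slope_ci95, ora$slope_ci95, tolerance = 1e-10)
  expect_true(fit$slope_ci95[1] <= fit$slope && fit$slope <= fit$slope_ci95[2])

  expect_error(fit_identity_regression(c(1, 2, 3), c(1, 1, 1)), "constant")
  expect_error(fit_identity_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("survey files round-trip exactly", {
  records <- data.frame(respondent_id = 1:3,
                        survey_day = as.Date("2015-03-04"),
                        gender = c("male", "female", "female"),
                        age = c(35L, 70L, 51L), time_in_venue = 60,
                        tsv = c(-0.12345678901234567, 0.5, 3),
                        clothing_clo = c(0.72, 1.01, 0.9),
                        preference = c(0L, -1L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(records, path)
  back <- read_survey(path)
  expect_identical(back$tsv, records$tsv)
  expect_equal(back$survey_day, records$survey_day)
})
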