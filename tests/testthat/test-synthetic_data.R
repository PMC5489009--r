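small_config <- function(...) {
  synthetic_config(n_days = 8, n_respondents = 96,
                   cell_counts = c(adult_male = 8, adult_female = 8,
                                   elderly_male = 16, elderly_female = 24),
                   ...)
}

test_that("the generator is fully deterministic under a seed", {
  a <- simulate_campaign(small_config(), seed = 11)
  b <- simulate_campaign(small_config(), seed = 11)
  expect_identical(a$survey, b$survey)
  expect_identical(a$outdoor, b$outdoor)
  expect_identical(a$truth, b$truth)
  c <- simulate_campaign(small_config(), seed = 12)
  expect_false(identical(a$survey$tsv, c$survey$tsv))
  expect_identical(names(a$survey), names(c$survey))
})

test_that("zero outdoor noise gives a smooth seasonal series", {
  out <- generate_outdoor_series(synthetic_config(outdoor_noise_sd = 0),
                                 seed = 1)
  expect_true(all(out$t_min <= out$t_max))
  expect_true(all(diff(out$date) == 1))
  r <- add_rmot(out)$rmot
  # pure sinusoid: day-to-day RMOT steps stay tiny
  expect_lt(max(abs(diff(r[!is.na(r)]))), 0.2)
})

test_that("the default campaign spans a wide RMOT range", {
  out <- generate_outdoor_series(synthetic_config(), seed = 3)
  r <- add_rmot(out)
  days <- synthetic_config()$start_date + 7 * (0:34)
  rmot <- r$rmot[match(days, r$date)]
  expect_false(anyNA(rmot))
  expect_gte(diff(range(rmot)), 10)
})

test_that("demographics hit the configured cell counts exactly", {
  resp <- generate_respondents(synthetic_config(), seed = 5)
  rec <- resp$records
  expect_equal(nrow(rec), 1121)
  cell <- function(a1, a2, g) sum(rec$age >= a1 & rec$age <= a2 & rec$gender == g)
  expect_equal(cell(30, 40, "male"), 60)
  expect_equal(cell(30, 40, "female"), 50)
  expect_equal(cell(65, 75, "male"), 128)
  expect_equal(cell(65, 75, "female"), 224)
  expect_gt(mean(rec$gender == "female"), 0.5)  # female-skewed venue
  # per-day allocation leaves at least 30 surveys per day
  expect_gte(min(table(rec$survey_day)), 30)
  expect_equal(length(unique(rec$survey_day)), 35)
})

test_that("true metabolic rates separate adults from elderly by about 10%", {
  resp <- generate_respondents(synthetic_config(), seed = 21)
  rec <- resp$records; m <- resp$truth$true_met_wm2
  for (g in c("male", "female")) {
    adult <- median(m[rec$age >= 30 & rec$age <= 40 & rec$gender == g])
    old <- median(m[rec$age >= 65 & rec$age <= 75 & rec$gender == g])
    pd <- percent_difference(adult, old)
    # systematic ~9.6% gap; the small adult cells leave the sample
    # median a few points of play around it
    expect_gt(pd, 2)
    expect_lt(pd, 17)
  }
})

test_that("indoor conditions respect the configured ranges", {
  cfg <- synthetic_config()
  ind <- generate_indoor_series(cfg, seed = 7)
  env <- daily_indoor_means(ind)
  expect_true(all(env$t_op >= cfg$indoor_temp_range[1] &
                    env$t_op <= cfg$indoor_temp_range[2]))
  expect_true(all(abs(env$rel_humidity - 0.5) < 0.05))
  expect_true(all(env$air_speed >= cfg$air_speed_range[1] &
                    env$air_speed <= cfg$air_speed_range[2]))
})

test_that("votes without noise or injected effect close the calibration loop", {
  cfg <- small_config(tsv_noise_sd = 0, true_beta_rmot = 0,
                      true_intercept = 0)
  camp <- simulate_campaign(cfg, seed = 31)
  cal <- calibrate_cohort(camp$survey, daily_indoor_means(camp$indoor))
  err <- abs(cal$results$met_rate_wm2 - camp$truth$true_met_wm2)
  expect_lt(max(err), 1e-2)
  expect_lt(max(cal$results$residual), 1e-5)
})

test_that("contamination feeds the filter; zero contamination passes clean", {
  clean <- simulate_campaign(small_config(contaminated_frac = 0), seed = 41)
  kept <- suppressMessages(filter_samples(clean$survey))
  expect_equal(nrow(kept), nrow(clean$survey))

  dirty <- simulate_campaign(small_config(contaminated_frac = 0.1), seed = 41)
  kept2 <- suppressMessages(filter_samples(dirty$survey))
  expect_equal(nrow(dirty$survey) - nrow(kept2),
               round(0.1 * nrow(dirty$survey)))
  log <- exclusion_log(kept2)
  expect_equal(sum(log$n), round(0.1 * nrow(dirty$survey)))
})

test_that("preference decreases with the sensation vote", {
  camp <- simulate_campaign(synthetic_config(), seed = 51)
  expect_lt(cor(camp$survey$tsv, camp$survey$preference), -0.5)
  expect_true(all(camp$survey$preference %in% -2:2))
  expect_true(all(camp$survey$tsv >= -3 & camp$survey$tsv <= 3))
})

test_that("emitted datasets round-trip exactly and keep truth separate", {
  camp <- simulate_campaign(small_config(), seed = 61)
  dir <- withr::local_tempdir()
  emit_dataset(camp, dir)
  expect_setequal(list.files(dir), c("survey.csv", "indoor_climate.csv",
                                     "outdoor_climate.csv", "truth.csv"))
  survey <- read_survey(file.path(dir, "survey.csv"))
  expect_identical(survey$tsv, camp$survey$tsv)
  expect_identical(survey$clothing_clo, camp$survey$clothing_clo)
  expect_equal(survey$survey_day, camp$survey$survey_day)
  indoor <- read_indoor_climate(file.path(dir, "indoor_climate.csv"))
  expect_identical(indoor$air_temp, camp$indoor$air_temp)
  outdoor <- read_outdoor_climate(file.path(dir, "outdoor_climate.csv"))
  expect_identical(outdoor$t_min, camp$outdoor$t_min)
  # the analysis readers never touch the truth sidecar
  expect_false("true_met_wm2" %in% names(survey))
})
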