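#' Basal metabolic rate from anthropometrics
#'
#' Harris-Benedict basal metabolic rate as revised by Roza and Shizgal,
#' converted from kcal/day to W with the conventional factor 0.0484:
#' males 0.0484 (13.397 W + 4.799 H - 5.677 A + 88.362),
#' females 0.0484 (9.247 W + 3.098 H - 4.330 A + 447.593),
#' with weight W in kg, height H in cm and age A in years.
#'
#' @param weight Body weight in kg (> 0).
#' @param height Body height in cm (> 0).
#' @param age Age in years (>= 0).
#' @param gender `"male"` or `"female"` (vectorised).
#' @return Basal metabolic rate in W.
#' @examples
#' bmr_watts(81, 180, 20, "male")
#' @export
bmr_watts <- function(weight, height, age, gender) {
  check_anthro(weight, height, age)
  gender <- match_gender(gender)
  kcal_day <- ifelse(
    gender == "male",
    13.397 * weight + 4.799 * height - 5.677 * age + 88.362,
    9.247 * weight + 3.098 * height - 4.330 * age + 447.593
  )
  0.0484 * kcal_day
}

match_gender <- function(gender) {
  gender <- as.character(gender)
  bad <- !gender %in% c("male", "female")
  if (any(bad))
    stop("unknown gender value(s): ", paste(unique(gender[bad]), collapse = ", "))
  gender
}

check_anthro <- function(weight, height, age) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be > 0")
  if (any(age < 0)) stop("age must be >= 0")
  invisible(TRUE)
}

#' DuBois body surface area
#'
#' BSA = 0.007184 weight^0.425 height^0.725, weight in kg, height in cm.
#'
#' @inheritParams bmr_watts
#' @return Body surface area in m2.
#' @examples
#' dubois_surface_area(83.2, 182.5)
#' @export
dubois_surface_area <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be > 0")
  0.007184 * weight^0.425 * height^0.725
}

#' Personal 1-Met heat equivalent
#'
#' The basal metabolic rate corresponds to about 0.8 Met (supine, fasted,
#' thermoneutral), so the heat equivalent of a 1-Met activity level for a
#' given person is BMR per unit DuBois surface area divided by 0.8. For a
#' standard young adult male this is close to the tabular 58 W/m2, but it
#' is substantially lower for females and for the elderly.
#'
#' @inheritParams bmr_watts
#' @return For `one_met_equivalent_wm2()`, the 1-Met heat equivalent in
#'   W/m2. For `met_rate_estimate()`, a data frame with `bmr_watts`,
#'   `surface_area` (m2), `bmr_per_area` (W/m2), `one_met_equivalent`
#'   (W/m2) and `met_units` (the equivalent expressed in Met).
#' @examples
#' one_met_equivalent_wm2(81, 180, 20, "male")    # ~58 W/m2
#' one_met_equivalent_wm2(69, 174, 20, "female")  # ~51 W/m2
#' @export
one_met_equivalent_wm2 <- function(weight, height, age, gender) {
  bmr_watts(weight, height, age, gender) /
    dubois_surface_area(weight, height) / 0.8
}

#' @rdname one_met_equivalent_wm2
#' @export
met_rate_estimate <- function(weight, height, age, gender) {
  bmr <- bmr_watts(weight, height, age, gender)
  bsa <- dubois_surface_area(weight, height)
  per_area <- bmr / bsa
  data.frame(
    bmr_watts = bmr,
    surface_area = bsa,
    bmr_per_area = per_area,
    one_met_equivalent = per_area / 0.8,
    met_units = wm2_to_met(per_area / 0.8)
  )
}

#' Reference anthropometrics for the Dutch adult and elderly population
#'
#' Average height and weight for the age categories 30-40 y and 65-75 y by
#' gender, shipped as a plain-text fixture. `age_midpoint` carries the
#' category midpoints (35 y and 70 y) used when an equation needs a
#' scalar age for the category.
#'
#' @return A data frame with columns `gender`, `age_group`, `height_cm`,
#'   `weight_kg`, `age_midpoint`.
#' @examples
#' reference_anthropometrics()
#' @export
reference_anthropometrics <- function() {
  path <- system.file("extdata", "dutch_reference_anthropometrics.csv",
                      package = "pmvcal", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$age_midpoint <- ifelse(tab$age_group == "30-40", 35, 70)
  tab
}
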