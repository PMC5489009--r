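#' Daily reference outdoor temperature
#'
#' The daily reference is the arithmetic mean of the day's minimum and
#' maximum outdoor temperature.
#'
#' @param t_min,t_max Daily minimum and maximum outdoor temperature,
#'   degrees C, with `t_min <= t_max`.
#' @return Reference temperature in degrees C.
#' @examples
#' daily_reference_temp(5, 15)
#' @export
daily_reference_temp <- function(t_min, t_max) {
  if (any(t_min > t_max)) stop("t_min must not exceed t_max")
  (t_min + t_max) / 2
}

#' Running mean outdoor temperature (RMOT)
#'
#' A four-day weighted mean of the daily reference temperatures,
#' (T_i + 0.8 T_{i-1} + 0.4 T_{i-2} + 0.2 T_{i-3}) / 2.4, where T_i is
#' the reference of the query day itself. The weights sum to the divisor,
#' so the RMOT is a convex combination of the four daily values.
#'
#' `running_mean_outdoor_temp()` computes the RMOT for one day;
#' `add_rmot()` appends `t_ref` and `rmot` columns for every day with
#' three days of history.
#'
#' @param series A data frame with columns `date` (Date or ISO-8601
#'   string), `t_min`, `t_max`; consecutive calendar days, no gaps.
#' @param day The query day (Date or ISO-8601 string).
#' @return `running_mean_outdoor_temp()`: RMOT in degrees C.
#'   `add_rmot()`: the series with `t_ref` and `rmot` columns (`rmot` is
#'   `NA` for the first three days).
#' @examples
#' s <- data.frame(date = as.Date("2015-03-01") + 0:3,
#'                 t_min = c(8, 10, 12, 14), t_max = c(12, 14, 16, 18))
#' running_mean_outdoor_temp(s, "2015-03-04")
#' @export
running_mean_outdoor_temp <- function(series, day) {
  series <- normalise_outdoor(series)
  day <- as.Date(day)
  need <- day - 3:0
  missing <- need[!need %in% series$date]
  if (length(missing))
    stop("insufficient outdoor history; missing date(s): ",
         paste(format(missing), collapse = ", "))
  tref <- series$t_ref[match(need, series$date)]
  sum(tref * c(0.2, 0.4, 0.8, 1)) / 2.4
}

#' @rdname running_mean_outdoor_temp
#' @export
add_rmot <- function(series) {
  series <- normalise_outdoor(series)
  n <- nrow(series)
  rmot <- rep(NA_real_, n)
  if (n >= 4) {
    t <- series$t_ref
    idx <- 4:n
    rmot[idx] <- (t[idx] + 0.8 * t[idx - 1] + 0.4 * t[idx - 2] +
                    0.2 * t[idx - 3]) / 2.4
  }
  series$rmot <- rmot
  series
}

# validate ordering, gaplessness and attach t_ref
normalise_outdoor <- function(series) {
  stopifnot(all(c("date", "t_min", "t_max") %in% names(series)))
  series$date <- as.Date(series$date)
  series <- series[order(series$date), , drop = FALSE]
  if (anyDuplicated(series$date)) stop("duplicated dates in outdoor series")
  if (nrow(series) > 1 && any(diff(series$date) != 1))
    stop("outdoor series has calendar gaps; consecutive days are required")
  series$t_ref <- daily_reference_temp(series$t_min, series$t_max)
  rownames(series) <- NULL
  series
}

#' Read and write outdoor daily climate files
#'
#' Plain delimited text with columns `date` (ISO-8601), `t_min`, `t_max`.
#' The writer adds the derived `t_ref` and `rmot` columns.
#'
#' @param path File path.
#' @param series Outdoor series data frame.
#' @return `read_outdoor_climate()` returns the validated series.
#' @export
read_outdoor_climate <- function(path) {
  normalise_outdoor(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_outdoor_climate
#' @export
write_outdoor_climate <- function(series, path) {
  out <- add_rmot(series)
  out$date <- format(out$date)
  write_precise_csv(out, path)
  invisible(path)
}
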