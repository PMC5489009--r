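# Delimited-text I/O helpers shared by the modules.

# write.csv loses precision through as.character (15 significant digits);
# format doubles with %.17g so a write/read round trip is bit-exact.
write_precise_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write survey record files
#'
#' One row per respondent, comma-delimited, header row, ISO-8601 dates.
#' Expected columns: `respondent_id`, `survey_day`, `gender`, `age`,
#' `time_in_venue`, `tsv`, `comfort`, `preference`, `acceptability`,
#' `clothing_clo`, `language` (extra columns pass through).
#'
#' @param path File path.
#' @param records Survey records data frame.
#' @return `read_survey()` returns a data frame with `survey_day` as
#'   `Date`.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("survey_day" %in% names(df)) df$survey_day <- as.Date(df$survey_day)
  df
}

#' @rdname read_survey
#' @export
write_survey <- function(records, path) {
  out <- records
  if ("survey_day" %in% names(out)) out$survey_day <- format(out$survey_day)
  write_precise_csv(out, path)
}

#' Read an indoor climate series
#'
#' Delimited text with columns `survey_day`, `air_temp`, `radiant_temp`,
#' `rel_humidity` (fraction), `air_speed`; one or more measurement rows
#' per day.
#'
#' @param path File path.
#' @export
read_indoor_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$survey_day <- as.Date(df$survey_day)
  df
}

#' Daily mean indoor environment
#'
#' Collapses an indoor climate series to one row per survey day by
#' averaging each environmental variable, the granularity at which the
#' analysis models PMV.
#'
#' @param indoor Indoor climate series (see [read_indoor_climate()]).
#' @return One row per `survey_day` with mean `air_temp`, `radiant_temp`,
#'   `rel_humidity`, `air_speed` and derived `t_op`.
#' @export
daily_indoor_means <- function(indoor) {
  sp <- split(indoor, as.character(indoor$survey_day))
  rows <- lapply(sp, function(d) {
    data.frame(
      survey_day = as.Date(d$survey_day[1]),
      air_temp = mean(d$air_temp),
      radiant_temp = mean(d$radiant_temp),
      rel_humidity = mean(d$rel_humidity),
      air_speed = mean(d$air_speed)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$survey_day), , drop = FALSE]
  out$t_op <- (out$air_temp + out$radiant_temp) / 2
  rownames(out) <- NULL
  out
}
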