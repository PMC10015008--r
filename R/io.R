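# CSV contract for runner-level race records and daily course weather.
# The regulator's native schema is not public, so the package defines a
# minimal explicit interchange format: ISO-8601 dates, 24 h "HH:MM" times,
# documented enums, one row per runner / per course-day.

.runner_cols <- c("horse_id", "meet_id", "course_id", "race_id", "date",
                  "off_time", "distance_yards", "race_type", "going_raw",
                  "age", "sex", "ehi")
.weather_cols <- c("course_id", "date", "tmax_c", "rh_pct")

.race_types <- c("flat", "jump")
.sexes <- c("filly", "colt", "gelding", "stallion", "rig")
# Official British going vocabulary: 7 turf + 3 all-weather categories.
# "standard to slow" is accepted as a synonym handled by collapse_going().
.goings_turf <- c("hard", "firm", "good to firm", "good", "good to soft",
                  "soft", "heavy")
.goings_aw <- c("fast", "standard", "standard to slow", "slow")
.goings_raw <- c(.goings_turf, .goings_aw)

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.bad_rows <- function(ok, field, what) {
  if (all(ok)) return(invisible())
  lines <- which(!ok)[1]
  stop(sprintf("%s: invalid value in field '%s' at data row %d",
               what, field, lines), call. = FALSE)
}

.parse_date <- function(x, field, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  .bad_rows(!is.na(d) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x), field, what)
  d
}

#' Read runner-level race records
#'
#' Reads and validates a `runners.csv` file with columns
#' `horse_id,meet_id,course_id,race_id,date,off_time,distance_yards,race_type,going_raw,age,sex,ehi`.
#' Dates are ISO-8601, off times 24 h `"HH:MM"`, `race_type` one of
#' flat/jump, `sex` one of filly/colt/gelding/stallion/rig, `going_raw` one of
#' the ten official going categories (plus the synonym "standard to slow"),
#' `ehi` 0/1. `(horse_id, race_id)` must be unique. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of validated runner records, one row per runner.
#' @seealso [write_runners()], [read_weather()]
#' @export
read_runners <- function(path) {
  if (!file.exists(path)) stop("read_runners: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_runners(df)
}

#' @rdname read_runners
#' @param df A data frame with the `runners.csv` columns (character or typed).
#' @export
validate_runners <- function(df) {
  what <- "runners"
  .check_columns(df, .runner_cols, what)
  df <- df[, .runner_cols, drop = FALSE]
  out <- data.frame(
    horse_id = as.character(df$horse_id),
    meet_id = as.character(df$meet_id),
    course_id = as.character(df$course_id),
    race_id = as.character(df$race_id),
    stringsAsFactors = FALSE
  )
  out$date <- .parse_date(as.character(df$date), "date", what)
  off <- as.character(df$off_time)
  .bad_rows(grepl("^([01]\\d|2[0-3]):[0-5]\\d$", off), "off_time", what)
  out$off_time <- off
  dist <- suppressWarnings(as.numeric(df$distance_yards))
  .bad_rows(!is.na(dist) & dist > 0, "distance_yards", what)
  out$distance_yards <- dist
  .bad_rows(as.character(df$race_type) %in% .race_types, "race_type", what)
  out$race_type <- as.character(df$race_type)
  .bad_rows(as.character(df$going_raw) %in% .goings_raw, "going_raw", what)
  out$going_raw <- as.character(df$going_raw)
  age <- suppressWarnings(as.integer(df$age))
  .bad_rows(!is.na(age) & age >= 1, "age", what)
  out$age <- age
  .bad_rows(as.character(df$sex) %in% .sexes, "sex", what)
  out$sex <- as.character(df$sex)
  ehi <- suppressWarnings(as.integer(df$ehi))
  .bad_rows(!is.na(ehi) & ehi %in% c(0L, 1L), "ehi", what)
  out$ehi <- ehi
  dup <- duplicated(paste(out$horse_id, out$race_id))
  if (any(dup)) {
    stop(sprintf("runners: duplicated (horse_id, race_id) at data row %d",
                 which(dup)[1]), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write runner records to CSV
#'
#' Inverse of [read_runners()]; `write_runners()` then `read_runners()` is a
#' lossless round trip.
#'
#' @param runners A runner record data frame (see [read_runners()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_runners <- function(runners, path) {
  runners <- validate_runners(runners)
  runners$date <- format(runners$date, "%Y-%m-%d")
  utils::write.csv(runners[, .runner_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily course weather records
#'
#' Reads and validates a `weather.csv` file with columns
#' `course_id,date,tmax_c,rh_pct`: one row per course per day, daily maximum
#' air temperature in degrees Celsius and relative humidity in percent.
#' Duplicate `(course_id, date)` keys and humidity outside `[0, 100]` are
#' rejected.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of validated weather records.
#' @seealso [write_weather()], [preceding_average()]
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("read_weather: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_weather(df)
}

#' @rdname read_weather
#' @param df A data frame with the `weather.csv` columns.
#' @export
validate_weather <- function(df) {
  what <- "weather"
  .check_columns(df, .weather_cols, what)
  out <- data.frame(course_id = as.character(df$course_id),
                    stringsAsFactors = FALSE)
  out$date <- .parse_date(as.character(df$date), "date", what)
  tmax <- suppressWarnings(as.numeric(df$tmax_c))
  .bad_rows(!is.na(tmax), "tmax_c", what)
  out$tmax_c <- tmax
  rh <- suppressWarnings(as.numeric(df$rh_pct))
  .bad_rows(!is.na(rh) & rh >= 0 & rh <= 100, "rh_pct", what)
  out$rh_pct <- rh
  dup <- duplicated(paste(out$course_id, out$date))
  if (any(dup)) {
    stop(sprintf("weather: duplicated (course_id, date) at data row %d",
                 which(dup)[1]), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_weather
#' @param weather A weather data frame.
#' @param path Output CSV path.
#' @export
write_weather <- function(weather, path) {
  weather <- validate_weather(weather)
  weather$date <- format(weather$date, "%Y-%m-%d")
  utils::write.csv(weather[, .weather_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
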