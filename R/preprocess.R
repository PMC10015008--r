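# Exclusion filters and derived model covariates: the analysis-ready model
# frame has one row per retained runner and no missing values in any model
# column.

.going5_levels <- c("firm", "good", "soft", "heavy", "standard")
.going_map <- c(
  "hard" = "firm", "firm" = "firm",
  "good to firm" = "good", "good" = "good",
  "good to soft" = "soft", "soft" = "soft",
  "heavy" = "heavy",
  "standard" = "standard", "standard to slow" = "standard", "slow" = "standard"
)

#' Collapse raw going categories to the five modelled levels
#'
#' The ten official going categories are reduced to five for model
#' convergence: firm, good, soft and heavy on turf, and standard for
#' all-weather surfaces. All-weather "fast" is not a modelled level: the few
#' meets run over fast ground are removed by [exclusion_filter()], and
#' passing `"fast"` here is an error.
#'
#' @param going_raw Character vector of raw going categories.
#' @return Factor with levels `firm, good, soft, heavy, standard`.
#' @examples
#' collapse_going(c("good to soft", "heavy", "standard to slow"))
#' @export
collapse_going <- function(going_raw) {
  going_raw <- as.character(going_raw)
  bad <- !(going_raw %in% names(.going_map))
  if (any(bad)) {
    stop(sprintf("collapse_going: unmapped going category '%s'",
                 going_raw[which(bad)[1]]), call. = FALSE)
  }
  factor(unname(.going_map[going_raw]), levels = .going5_levels)
}

#' Race off-time band (pre vs post 5 p.m.)
#'
#' Races starting at or after 17:00 are "post5pm" (evening races, typically
#' cooler), earlier races "pre5pm". The 17:00 boundary itself is assigned to
#' post5pm ("after 5 p.m." read inclusively).
#'
#' @param off_time Character vector of 24 h `"HH:MM"` times.
#' @return Factor with levels `pre5pm, post5pm`.
#' @examples
#' derive_off_band(c("14:30", "17:00", "19:05"))
#' @export
derive_off_band <- function(off_time) {
  m <- .off_minutes(off_time)
  factor(ifelse(m >= 17L * 60L, "post5pm", "pre5pm"),
         levels = c("pre5pm", "post5pm"))
}

.off_minutes <- function(off_time) {
  ok <- grepl("^([01]\\d|2[0-3]):[0-5]\\d$", off_time)
  if (any(!ok)) {
    stop("derive_off_band: off_time must be 24 h 'HH:MM'", call. = FALSE)
  }
  as.integer(substr(off_time, 1, 2)) * 60L + as.integer(substr(off_time, 4, 5))
}

#' Previous-incident flag per runner
#'
#' For each run, 1 if the same horse has at least one EHI-positive run
#' strictly earlier in (date, off_time) order, else 0. A run's own outcome
#' never feeds its own flag (strictly-prior definition, preventing response
#' leakage), so the flag is 0 up to and including a horse's first EHI run and
#' 1 afterwards. Two runs by one horse at an identical (date, off_time) leave
#' the ordering undefined and raise an error.
#'
#' @param runners Runner records (see [read_runners()]).
#' @return Integer vector of 0/1 flags aligned with `runners` rows.
#' @export
derive_previous_incident <- function(runners) {
  n <- nrow(runners)
  mins <- .off_minutes(runners$off_time)
  ord <- order(runners$horse_id, runners$date, mins)
  h <- runners$horse_id[ord]
  key <- paste(h, runners$date[ord], mins[ord])
  if (any(duplicated(key))) {
    stop("derive_previous_incident: a horse has two runs at the same date and off_time; ordering undefined",
         call. = FALSE)
  }
  e <- runners$ehi[ord]
  cum <- ave(e, h, FUN = cumsum)
  prior <- as.integer((cum - e) > 0)
  out <- integer(n)
  out[ord] <- prior
  out
}

#' Apply the study exclusion rules
#'
#' Removes, in order: (1) rig horses; (2) all runners at meets run over
#' all-weather "fast" going; (3) runners with a missing value in any model
#' covariate. Returns the retained rows plus a per-rule exclusion log.
#'
#' @param frame A data frame holding at least `sex`, `going_raw`, `meet_id`
#'   and the model covariate columns listed in `model_cols`.
#' @param model_cols Character vector of columns checked for missingness.
#' @return A list with `frame` (retained rows) and `log` (named integer
#'   vector with counts removed per rule: `rig`, `fast_meet`, `missing`).
#' @export
exclusion_filter <- function(frame,
                             model_cols = intersect(
                               c("ehi", "distance_yards", "wbgt_c", "prev5_c",
                                 "age", "prev_incident", "going5", "year",
                                 "off_band", "race_type", "sex"),
                               names(frame))) {
  log <- c(rig = 0L, fast_meet = 0L, missing = 0L)
  keep <- frame$sex != "rig"
  log["rig"] <- sum(!keep)
  frame <- frame[keep, , drop = FALSE]
  fast_meets <- unique(frame$meet_id[frame$going_raw == "fast"])
  keep <- !(frame$meet_id %in% fast_meets)
  log["fast_meet"] <- sum(!keep)
  frame <- frame[keep, , drop = FALSE]
  complete <- !Reduce(`|`, lapply(frame[model_cols], is.na))
  log["missing"] <- sum(!complete)
  frame <- frame[complete, , drop = FALSE]
  rownames(frame) <- NULL
  list(frame = frame, log = log)
}

#' Build the analysis-ready model frame
#'
#' Joins runner records to race-day weather by (course_id, date), derives the
#' model covariates (WBGT, preceding 5-day temperature average,
#' previous-incident flag, collapsed going, off-time band, year), and applies
#' the exclusion rules. The result has no missing values in any model column;
#' the per-rule exclusion log is attached as attribute `"exclusion_log"`.
#'
#' Runners at meets with no weather row (or an incomplete preceding window)
#' get missing environmental covariates and are removed by the missing-data
#' rule, with their count logged.
#'
#' @param runners Runner records (see [read_runners()]).
#' @param weather Weather records (see [read_weather()]).
#' @param window Preceding-average window in days (default 5).
#' @return A `data.frame` with columns `ehi`, `distance_yards`, `wbgt_c`,
#'   `prev5_c`, `age`, `prev_incident` (factor no/yes), `going5`, `year`,
#'   `off_band`, `race_type`, `sex`, `horse_id`, `meet_id`, `race_id`,
#'   `course_id`, `date`, plus attribute `exclusion_log`.
#' @export
build_model_frame <- function(runners, weather, window = 5L) {
  runners <- validate_runners(runners)
  weather <- validate_weather(weather)
  frame <- runners
  wkey <- paste(weather$course_id, weather$date)
  idx <- match(paste(frame$course_id, frame$date), wkey)
  tmax <- weather$tmax_c[idx]
  rh <- weather$rh_pct[idx]
  frame$wbgt_c <- ifelse(is.na(tmax) | is.na(rh), NA_real_,
                         wbgt_from_weather(ifelse(is.na(tmax), 0, tmax),
                                           ifelse(is.na(rh), 0, rh)))
  frame$prev5_c <- preceding_average(weather, frame$course_id, frame$date,
                                     window = window)
  frame$prev_incident <- factor(
    ifelse(derive_previous_incident(frame) == 1L, "yes", "no"),
    levels = c("no", "yes"))
  frame$off_band <- derive_off_band(frame$off_time)
  frame$year <- factor(format(frame$date, "%Y"))
  excl <- exclusion_filter(frame)
  frame <- excl$frame
  frame$going5 <- collapse_going(frame$going_raw)
  frame$race_type <- factor(frame$race_type, levels = .race_types)
  frame$sex <- factor(frame$sex, levels = setdiff(.sexes, "rig"))
  cols <- c("ehi", "distance_yards", "wbgt_c", "prev5_c", "age",
            "prev_incident", "going5", "year", "off_band", "race_type",
            "sex", "horse_id", "meet_id", "race_id", "course_id", "date")
  frame <- frame[, cols]
  attr(frame, "exclusion_log") <- excl$log
  frame
}
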