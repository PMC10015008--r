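#' Wet-bulb temperature from air temperature and relative humidity
#'
#' Stull's arctangent approximation of the adiabatic-saturation (wet-bulb)
#' temperature, valid for standard sea-level pressure. Angles are in radians
#' and relative humidity is entered in percent (50, not 0.5); this is the
#' convention under which the published formula reproduces Stull's tables.
#'
#' @param temp_c Air temperature in degrees Celsius. Values outside the
#'   physically plausible range (-20, 50) are rejected.
#' @param rh_pct Relative humidity in percent, in `[0, 100]`.
#' @return Wet-bulb temperature in degrees Celsius, vectorised over inputs.
#' @examples
#' wet_bulb_temperature(20, 50)
#' @seealso [black_globe_temperature()], [wbgt_index()]
#' @export
wet_bulb_temperature <- function(temp_c, rh_pct) {
  if (any(!is.finite(temp_c)) || any(!is.finite(rh_pct))) {
    stop("wet_bulb_temperature: non-finite input", call. = FALSE)
  }
  if (any(rh_pct < 0 | rh_pct > 100)) {
    stop("wet_bulb_temperature: relative humidity must be in [0, 100] percent",
         call. = FALSE)
  }
  if (any(temp_c <= -20 | temp_c >= 50)) {
    stop("wet_bulb_temperature: air temperature outside plausible range (-20, 50) degC",
         call. = FALSE)
  }
  temp_c * atan(0.151977 * sqrt(rh_pct + 8.313659)) +
    atan(temp_c + rh_pct) -
    atan(rh_pct - 1.676331) +
    0.00391838 * rh_pct^1.5 * atan(0.023101 * rh_pct) -
    4.686035
}

#' Black-globe temperature estimated from air temperature
#'
#' Linear approximation of the black-globe (radiant-loaded) temperature used
#' when no globe thermometer measurement is available.
#'
#' @param temp_c Air temperature in degrees Celsius.
#' @return Estimated black-globe temperature in degrees Celsius.
#' @examples
#' black_globe_temperature(20)
#' @export
black_globe_temperature <- function(temp_c) {
  1.54 * temp_c + 8.65
}

#' Wet bulb globe temperature index
#'
#' The WBGT heat-stress index as the fixed weighted sum of wet-bulb and
#' black-globe temperatures (no direct solar term, as appropriate for an
#' estimate without radiation measurements).
#'
#' @param twb_c Wet-bulb temperature, degrees Celsius.
#' @param tg_c Black-globe temperature, degrees Celsius.
#' @return WBGT in degrees Celsius: `0.7 * twb_c + 0.3 * tg_c`.
#' @examples
#' wbgt_index(wet_bulb_temperature(30, 80), black_globe_temperature(30))
#' @export
wbgt_index <- function(twb_c, tg_c) {
  0.7 * twb_c + 0.3 * tg_c
}

#' WBGT estimated from daily air temperature and relative humidity
#'
#' Convenience composition: wet-bulb from `temp_c` and `rh_pct`, black-globe
#' from `temp_c`, then the WBGT index.
#'
#' @inheritParams wet_bulb_temperature
#' @return WBGT in degrees Celsius.
#' @export
wbgt_from_weather <- function(temp_c, rh_pct) {
  wbgt_index(wet_bulb_temperature(temp_c, rh_pct),
             black_globe_temperature(temp_c))
}

#' Preceding n-day average of daily maximum temperature
#'
#' Mean daily maximum temperature at a course over the `window` days strictly
#' before `date` (the race day itself is excluded). Used as an acclimatisation
#' covariate: horses racing after a warm spell are expected to tolerate heat
#' better. If any day of the window is missing from the weather table the
#' result is `NA` (a missing-covariate marker; such runners are later
#' excluded) rather than a silently shortened mean.
#'
#' @param weather A weather table as returned by [read_weather()] (columns
#'   `course_id`, `date`, `tmax_c`, `rh_pct`).
#' @param course_id Course identifier(s), recycled against `date`.
#' @param date Race date(s) (`Date`).
#' @param window Number of preceding days to average (default 5).
#' @return Numeric vector of mean preceding maximum temperatures (degrees
#'   Celsius), `NA` where the window is incomplete.
#' @examples
#' w <- data.frame(course_id = "C1",
#'                 date = as.Date("2016-07-01") + 0:5,
#'                 tmax_c = c(20, 22, 24, 26, 28, 30), rh_pct = 60)
#' preceding_average(w, "C1", as.Date("2016-07-06"))
#' @export
preceding_average <- function(weather, course_id, date, window = 5L) {
  stopifnot(window >= 1L)
  n <- max(length(course_id), length(date))
  course_id <- rep_len(as.character(course_id), n)
  date <- rep_len(as.Date(date), n)
  key <- paste(weather$course_id, as.integer(as.Date(weather$date)))
  out <- numeric(n)
  acc <- matrix(NA_real_, n, window)
  for (k in seq_len(window)) {
    idx <- match(paste(course_id, as.integer(date) - k), key)
    acc[, k] <- weather$tmax_c[idx]
  }
  out <- rowMeans(acc)
  out
}
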