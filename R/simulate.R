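# Synthetic race populations with the statistical structure the analysis
# assumes: repeated runs per horse, runners clustered in race meets sharing
# weather, smooth covariate effects on the log-odds scale, categorical
# effects, horse/meet random intercepts, and a sequentially updated
# previous-incident state. Ground truth is returned for recovery testing.
#
# Default effect sizes are anchored so that the headline contrasts hold
# exactly on the log-odds scale: OR 5.66 for 3520 vs 1760 yd, 10.14 for WBGT
# 30 vs 20 degC, 0.33 for a preceding 5-day average of 25 vs 15 degC, 1.34
# for age 4 vs 2, 0.82 for age 6 vs 4, 18.59 for a previous incident and
# 1.478 for pre- vs post-5 p.m. off times. Effect shapes are piecewise-linear
# interpolants through anchor points so the truth is basis-independent.

# Effect shapes: piecewise-linear anchor tables whose anchor points lie on
# smooth, low-curvature curves, subject to the pinned two-point contrasts and
# the reported qualitative behaviour (distance rising then flattening over
# jump distances; WBGT rising gently in the cold range and at 10.14-fold odds
# per 10 degC in the warm range; preceding 5-day average linearly protective;
# age peaking near 4 then declining). Each pinned contrast spans a single
# constant-slope segment, and slope changes are spread over several anchors:
# sharp corners are avoided deliberately, because penalized smoothers round
# corners and redistribute their curvature, which would bias anchored
# parameter recovery for reasons unrelated to the pipeline under test.
.default_truth_tables <- function() {
  s_d <- log(5.66) / 1760       # distance slope per yard over flat distances
  s_w <- log(10.14) / 10        # WBGT slope per degC in the warm range
  # age: parabola through the pinned points f(2)=0, f(4)=ln 1.34,
  # f(6)=ln 1.34 + ln 0.82, i.e. f(x) = b (x-2) + c (x^2-4)
  c_a <- (log(0.82) - log(1.34)) / 8
  b_a <- (log(1.34) - 12 * c_a) / 2
  f_a <- function(x) b_a * (x - 2) + c_a * (x^2 - 4)
  list(
    distance_yards = data.frame(
      # constant pinned slope across (and beyond) the anchored 1760-3520 yd
      # interval, with the slope decay placed away from its endpoints
      x = c(880, 4200, 5280, 7040),
      f = cumsum(c(0, s_d * 3320, 0.0006 * 1080, 0.0003 * 1760))),
    wbgt_c = data.frame(
      x = c(-12, 0, 6, 10, 14, 18, 20, 30, 48),
      f = cumsum(c(0, 0.05 * 12, 0.08 * 6, 0.12 * 4, 0.16 * 4, 0.20 * 4,
                   0.22 * 2, s_w * 10, s_w * 18))),
    prev5_c = data.frame(                 # linear, ln(0.33)/10 degC^-1
      x = c(-6, 40),
      f = log(0.33) / 10 * c(-6 - 15, 40 - 15)),
    age = data.frame(                     # smooth peak at ~4, mild linear
      x = c(1:7, 15),                     # decline for veteran ages
      f = c(f_a(1:7), f_a(7) - 8 * 0.12))
  )
}

#' Configuration for the synthetic race-population generator
#'
#' Bundles the population design (counts, date range, meet structure) and the
#' ground-truth effect sizes on the log-odds scale. Defaults emulate the
#' analysed British study population: ~620,000 runners over July 2010 to
#' April 2018 at 0.1% EHI prevalence, with smooth effect truths anchored at
#' the headline odds-ratio contrasts (see package vignette).
#'
#' @param n_runners Target number of runners (rows) in the population.
#' @param n_horses Number of horses (careers of repeated runs).
#' @param n_courses Number of racecourses.
#' @param aw_course_frac Fraction of courses with an all-weather surface.
#' @param date_start,date_end Date range of race meets.
#' @param prevalence_target Expected EHI prevalence the intercept is
#'   calibrated to by bisection (default 0.001).
#' @param runners_per_meet Average runners per race meet (sets the meet count).
#' @param evening_meet_frac Fraction of flat meets starting in the evening.
#' @param prob_fast_meet Probability an all-weather meet is run over "fast"
#'   going (such meets are removed by the exclusion filter).
#' @param rig_frac Probability a horse is a rig (removed by the filter).
#' @param smooth_truths Named list of piecewise-linear truth tables
#'   (data frames with columns `x`, `f`) for `distance_yards`, `wbgt_c`,
#'   `prev5_c` and `age`; `NULL` entries mean a zero effect.
#' @param beta_prev Log-odds effect of a previous EHI incident.
#' @param beta_off Named log-odds effects for off-time bands
#'   (`pre5pm`, `post5pm`).
#' @param beta_going Named log-odds effects for the five going levels.
#' @param beta_year Named log-odds effects per calendar year.
#' @param sigma_horse,sigma_meet Random-intercept standard deviations.
#' @param seed Integer master seed for the generator.
#' @return An object of class `ehi_generator_config` (a validated list).
#' @export
generator_config <- function(n_runners = 620000L,
                             n_horses = 45000L,
                             n_courses = 60L,
                             aw_course_frac = 0.15,
                             date_start = as.Date("2010-07-01"),
                             date_end = as.Date("2018-04-30"),
                             prevalence_target = 0.001,
                             runners_per_meet = 70,
                             evening_meet_frac = 0.25,
                             prob_fast_meet = 0.002,
                             rig_frac = 0.001,
                             smooth_truths = .default_truth_tables(),
                             beta_prev = log(18.59),
                             beta_off = c(pre5pm = log(1.478), post5pm = 0),
                             beta_going = c(firm = 0, good = 0.529,
                                            soft = 0.753, heavy = 0.853,
                                            standard = -0.201),
                             beta_year = NULL,
                             sigma_horse = 0.3,
                             sigma_meet = 0.2,
                             seed = 1L) {
  stopifnot(n_runners >= 100, n_horses >= 10, n_courses >= 2,
            prevalence_target > 0, prevalence_target < 0.5,
            sigma_horse >= 0, sigma_meet >= 0,
            date_end > date_start)
  years <- seq(as.integer(format(date_start, "%Y")),
               as.integer(format(date_end, "%Y")))
  if (is.null(beta_year)) {
    # elevated incidence in the two final (warm) years, as reported
    beta_year <- setNames(rep(0, length(years)), years)
    beta_year[as.character(intersect(c(2017, 2018), years))] <-
      c(0.47, 0.83)[seq_along(intersect(c(2017, 2018), years))]
  }
  cfg <- list(n_runners = as.integer(n_runners), n_horses = as.integer(n_horses),
              n_courses = as.integer(n_courses), aw_course_frac = aw_course_frac,
              date_start = as.Date(date_start), date_end = as.Date(date_end),
              prevalence_target = prevalence_target,
              runners_per_meet = runners_per_meet,
              evening_meet_frac = evening_meet_frac,
              prob_fast_meet = prob_fast_meet, rig_frac = rig_frac,
              smooth_truths = smooth_truths, beta_prev = beta_prev,
              beta_off = beta_off, beta_going = beta_going,
              beta_year = beta_year, sigma_horse = sigma_horse,
              sigma_meet = sigma_meet, seed = as.integer(seed))
  class(cfg) <- "ehi_generator_config"
  cfg
}

#' Simulate daily course weather
#'
#' Per course and day: daily maximum temperature as a seasonal sinusoid (UK
#' climate scale: winter ~7, summer ~21 degC) plus a course offset and AR(1)
#' noise, clipped to (-5, 38); relative humidity negatively correlated with
#' temperature, clipped to `[20, 100]`. The series starts `window + 2` days
#' before `date_start` so preceding-average windows are complete.
#'
#' @param config An [generator_config()] object.
#' @param window Preceding-average window the series must cover (default 5).
#' @return A weather data frame in the [read_weather()] schema.
#' @export
simulate_weather <- function(config, window = 5L) {
  set.seed(config$seed)
  dates <- seq(config$date_start - (window + 2L), config$date_end, by = "day")
  nd <- length(dates)
  course_id <- sprintf("C%02d", seq_len(config$n_courses))
  doy <- as.integer(format(dates, "%j"))
  seasonal <- 13.5 + 7.5 * cos(2 * pi * (doy - 197) / 365.25)
  out <- vector("list", config$n_courses)
  for (i in seq_len(config$n_courses)) {
    offset <- rnorm(1, 0, 1)
    innov <- rnorm(nd, 0, 3 * sqrt(1 - 0.7^2))
    ar <- as.numeric(stats::filter(innov, 0.7, method = "recursive"))
    tmax <- pmin(pmax(seasonal + offset + ar, -5), 38)
    rh <- pmin(pmax(80 - 1.1 * (tmax - 14) + rnorm(nd, 0, 8), 20), 100)
    out[[i]] <- data.frame(course_id = course_id[i], date = dates,
                           tmax_c = round(tmax, 2), rh_pct = round(rh, 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.pwl <- function(table, x) {
  if (is.null(table)) return(rep(0, length(x)))
  y <- approx(table$x, table$f, xout = x, rule = 1)$y
  if (any(is.na(y) & !is.na(x))) {
    stop("covariate outside the generator's truth-table support", call. = FALSE)
  }
  y
}

#' Simulate a race population with known ground truth
#'
#' Builds race meets (course, date, going, race off times), races (distance,
#' type) and horse careers (repeated runs with advancing age), derives each
#' runner's true log-odds of EHI from the configured effect truths plus
#' horse/meet random intercepts, calibrates the intercept by bisection so the
#' expected prevalence matches `prevalence_target`, and draws outcomes
#' sequentially per horse in date order so the previous-incident state
#' updates after each simulated EHI.
#'
#' @param config An [generator_config()] object.
#' @return A list with `runners` (the [read_runners()] schema), `weather`
#'   (the [read_weather()] schema) and `truth`, an `ehi_truth` object holding
#'   the resolved intercept, effect tables/coefficients, realised random
#'   intercepts, and the per-runner true linear predictor (`truth$eta`,
#'   aligned with `runners` rows).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "ehi_generator_config"))
  weather <- simulate_weather(config)
  set.seed((config$seed %% 2147483000L) + 1L)

  ## courses -----------------------------------------------------------
  n_courses <- config$n_courses
  course_id <- sprintf("C%02d", seq_len(n_courses))
  n_aw <- max(1L, round(config$aw_course_frac * n_courses))
  surface <- rep("turf", n_courses)
  surface[seq_len(n_aw)] <- "aw"

  ## meets --------------------------------------------------------------
  n_meets <- ceiling(config$n_runners * 1.03 / config$runners_per_meet)
  dates <- seq(config$date_start, config$date_end, by = "day")
  month <- as.integer(format(dates, "%m"))
  date_w <- ifelse(month %in% 4:9, 1.4, 0.7)
  meet <- data.frame(
    meet_id = sprintf("M%06d", seq_len(n_meets)),
    course = sample.int(n_courses, n_meets, replace = TRUE),
    date = sample(dates, n_meets, replace = TRUE, prob = date_w),
    stringsAsFactors = FALSE)
  meet$course_id <- course_id[meet$course]
  meet$surface <- surface[meet$course]
  meet$type <- ifelse(meet$surface == "aw", "flat",
                      sample(c("flat", "jump"), n_meets, replace = TRUE))
  summer <- as.integer(format(meet$date, "%m")) %in% 4:8
  meet$evening <- meet$type == "flat" & summer &
    runif(n_meets) < config$evening_meet_frac

  ## meet-level weather and going ---------------------------------------
  wkey <- paste(weather$course_id, weather$date)
  widx <- match(paste(meet$course_id, meet$date), wkey)
  meet$tmax <- weather$tmax_c[widx]
  meet$rh <- weather$rh_pct[widx]
  wetness <- 0.04 * (meet$rh - 75) - 0.06 * (meet$tmax - 14) + rnorm(n_meets, 0, 0.5)
  turf5 <- cut(wetness, c(-Inf, -0.81, 0.20, 1.0, Inf),
               labels = c("firm", "good", "soft", "heavy"))
  raw_from5 <- function(g5) {
    switch(as.character(g5),
           firm = sample(c("hard", "firm"), 1, prob = c(.1, .9)),
           good = sample(c("good to firm", "good"), 1, prob = c(.4, .6)),
           soft = sample(c("good to soft", "soft"), 1, prob = c(.5, .5)),
           heavy = "heavy")
  }
  meet$going_raw <- ifelse(
    meet$surface == "aw",
    ifelse(runif(n_meets) < config$prob_fast_meet, "fast",
           sample(c("standard", "standard to slow", "slow"), n_meets,
                  replace = TRUE, prob = c(.8, .12, .08))),
    vapply(turf5, raw_from5, character(1)))

  ## races --------------------------------------------------------------
  races_per_meet <- sample(6:8, n_meets, replace = TRUE)
  race_meet <- rep(seq_len(n_meets), races_per_meet)
  race_no <- sequence(races_per_meet)
  n_races <- length(race_meet)
  start_min <- ifelse(meet$evening[race_meet], 16L * 60L + 35L, 13L * 60L + 55L)
  off_min <- start_min + (race_no - 1L) * 35L
  is_jump <- meet$type[race_meet] == "jump"
  furlongs <- integer(n_races)
  nf <- sum(!is_jump)
  furlongs[!is_jump] <- sample(5:16, nf, replace = TRUE,
                               prob = c(3, 4, 5, 5, 4, 3, 2, 2, 1.5, 1, 1, 1))
  furlongs[is_jump] <- sample(16:32, sum(is_jump), replace = TRUE,
                              prob = c(4, 4, 4, 3, 3, 3, 2.5, 2.5, 2, 2,
                                       1.5, 1.5, 1, 1, 1, 0.7, 0.5))
  race <- data.frame(
    race_id = sprintf("R%07d", seq_len(n_races)),
    meet = race_meet,
    off_min = off_min,
    distance_yards = 220 * furlongs,
    race_type = ifelse(is_jump, "jump", "flat"),
    stringsAsFactors = FALSE)

  ## horses -------------------------------------------------------------
  n_horses <- config$n_horses
  horse_id <- sprintf("H%06d", seq_len(n_horses))
  p_jump_slots <- mean(is_jump)
  horse_disc <- ifelse(runif(n_horses) < p_jump_slots, "jump", "flat")
  runs_mean <- config$n_runners / n_horses
  n_runs <- 1L + rnbinom(n_horses, size = 1.3, mu = max(runs_mean - 1, 0.5))
  sexes <- c("filly", "colt", "gelding", "stallion", "rig")
  sex_p <- c(0.28, 0.22, 0.44, 0.06 - config$rig_frac, config$rig_frac)
  horse_sex <- sample(sexes, n_horses, replace = TRUE, prob = sex_p)

  ## assign runs to race slots -----------------------------------------
  field_size <- sample(7:13, n_races, replace = TRUE)
  slot_race <- rep(seq_len(n_races), field_size)
  runs <- NULL
  for (disc in c("flat", "jump")) {
    slots <- sample(slot_race[race$race_type[slot_race] == disc])
    hs <- which(horse_disc == disc)
    pool <- sample(rep(hs, n_runs[hs]))
    k <- min(length(slots), length(pool))
    runs <- rbind(runs, data.frame(race = slots[seq_len(k)],
                                   horse = pool[seq_len(k)]))
  }
  runs$meet <- race$meet[runs$race]
  runs$date <- meet$date[runs$meet]
  runs <- runs[!duplicated(paste(runs$horse, runs$race)) &
                 !duplicated(paste(runs$horse, runs$date)), ]
  if (nrow(runs) > config$n_runners) {
    runs <- runs[sort(sample.int(nrow(runs), config$n_runners)), ]
  }
  n <- nrow(runs)

  ## ages: birth year anchored at each horse's first run year ----------
  run_year <- as.integer(format(runs$date, "%Y"))
  first_year <- tapply(run_year, runs$horse, min)
  hids <- as.integer(names(first_year))
  offs <- ifelse(horse_disc[hids] == "flat",
                 sample(2:6, length(hids), replace = TRUE,
                        prob = c(.35, .3, .2, .1, .05)),
                 sample(4:7, length(hids), replace = TRUE,
                        prob = c(.35, .3, .25, .1)))
  birth <- rep(NA_integer_, n_horses)
  birth[hids] <- as.integer(first_year) - offs
  age <- run_year - birth[runs$horse]

  ## true linear predictor ---------------------------------------------
  b_horse <- rnorm(n_horses, 0, config$sigma_horse)
  b_meet <- rnorm(n_meets, 0, config$sigma_meet)
  wbgt <- wbgt_from_weather(meet$tmax, meet$rh)[runs$meet]
  prev5 <- preceding_average(weather, meet$course_id[runs$meet], runs$date)
  going5 <- as.character(collapse_going(
    ifelse(meet$going_raw == "fast", "standard", meet$going_raw)))[runs$meet]
  off_band <- ifelse(race$off_min[runs$race] >= 17L * 60L, "post5pm", "pre5pm")
  st <- config$smooth_truths
  eta_rest <- .pwl(st$distance_yards, race$distance_yards[runs$race]) +
    .pwl(st$wbgt_c, wbgt) + .pwl(st$prev5_c, prev5) + .pwl(st$age, age) +
    unname(config$beta_going[going5]) +
    unname(config$beta_year[as.character(run_year)]) +
    unname(config$beta_off[off_band]) +
    b_horse[runs$horse] + b_meet[runs$meet]

  ## Calibrate the intercept on the exact expected prevalence of the
  ## sequential process: within a horse's ordered runs, with s_{j-1} the
  ## probability of no event among the first j-1 runs,
  ## P(event at run j) = s_{j-1} p0_j + (1 - s_{j-1}) p1_j.
  ord0 <- order(runs$horse, runs$date)
  er <- eta_rest[ord0]
  new_horse <- c(TRUE, runs$horse[ord0][-1] != runs$horse[ord0][-n])
  grp_starts <- which(new_horse)
  group_cumsum <- function(v) {
    cs <- cumsum(v)
    offset <- rep(c(0, cs[grp_starts[-1] - 1L]), diff(c(grp_starts, n + 1L)))
    cs - offset
  }
  expected_prev <- function(a) {
    p0 <- plogis(a + er)
    p1 <- plogis(a + er + config$beta_prev)
    cum_log_s <- group_cumsum(log1p(-p0))
    s_prev <- exp(cum_log_s - log1p(-p0))  # s_{j-1}: excludes the current run
    mean(s_prev * p0 + (1 - s_prev) * p1)
  }
  f <- function(a) expected_prev(a) - config$prevalence_target
  if (f(-30) > 0 || f(5) < 0) {
    stop("simulate_population: cannot bracket the intercept for the requested prevalence",
         call. = FALSE)
  }
  alpha <- uniroot(f, c(-30, 5), tol = 1e-8)$root
  eta0 <- alpha + eta_rest

  ## sequential outcomes with previous-incident updating ----------------
  ord <- order(runs$horse, runs$date)
  u <- runif(n)
  hit0 <- u < plogis(eta0)
  hit1 <- u < plogis(eta0 + config$beta_prev)
  h <- runs$horse[ord]
  cum0 <- ave(as.integer(hit0[ord]), h, FUN = cumsum)
  after_first <- (cum0 - as.integer(hit0[ord])) > 0
  ehi_ord <- ifelse(after_first, hit1[ord], hit0[ord])
  ehi <- integer(n); ehi[ord] <- as.integer(ehi_ord)
  prev_flag <- integer(n); prev_flag[ord] <- as.integer(after_first)
  eta <- eta0 + config$beta_prev * prev_flag

  runners <- data.frame(
    horse_id = horse_id[runs$horse],
    meet_id = meet$meet_id[runs$meet],
    course_id = meet$course_id[runs$meet],
    race_id = race$race_id[runs$race],
    date = runs$date,
    off_time = sprintf("%02d:%02d", race$off_min[runs$race] %/% 60L,
                       race$off_min[runs$race] %% 60L),
    distance_yards = race$distance_yards[runs$race],
    race_type = race$race_type[runs$race],
    going_raw = meet$going_raw[runs$meet],
    age = age,
    sex = horse_sex[runs$horse],
    ehi = ehi,
    stringsAsFactors = FALSE)

  truth <- list(alpha = alpha,
                smooth_truths = st,
                beta_prev = config$beta_prev,
                beta_off = config$beta_off,
                beta_going = config$beta_going,
                beta_year = config$beta_year,
                sigma_horse = config$sigma_horse,
                sigma_meet = config$sigma_meet,
                b_horse = setNames(b_horse, horse_id),
                b_meet = setNames(b_meet, meet$meet_id),
                eta = eta,
                prev_flag = prev_flag,
                prevalence = mean(ehi))
  class(truth) <- "ehi_truth"
  list(runners = runners, weather = weather, truth = truth)
}

#' True linear predictor from generator ground truth
#'
#' Recomputes the simulated log-odds for arbitrary covariate rows from the
#' stored truth (for oracle comparisons). Covariates must lie within the
#' truth tables' support; unknown horse/meet identifiers contribute a zero
#' random intercept only when `strict = FALSE`.
#'
#' @param truth An `ehi_truth` object from [simulate_population()].
#' @param covariates Data frame with columns `distance_yards`, `wbgt_c`,
#'   `prev5_c`, `age`, `going5`, `year`, `off_band`, `prev_incident`
#'   (0/1 or "no"/"yes"), and optionally `horse_id`, `meet_id`.
#' @param strict Error on unknown horse/meet ids (default `TRUE`).
#' @return Numeric vector of log-odds.
#' @export
true_linear_predictor <- function(truth, covariates, strict = TRUE) {
  stopifnot(inherits(truth, "ehi_truth"))
  st <- truth$smooth_truths
  prev <- covariates$prev_incident
  if (is.factor(prev) || is.character(prev)) prev <- as.integer(prev == "yes")
  yr <- as.character(covariates$year)
  if (any(!yr %in% names(truth$beta_year))) {
    stop("true_linear_predictor: year outside generator support", call. = FALSE)
  }
  eta <- truth$alpha +
    .pwl(st$distance_yards, covariates$distance_yards) +
    .pwl(st$wbgt_c, covariates$wbgt_c) +
    .pwl(st$prev5_c, covariates$prev5_c) +
    .pwl(st$age, covariates$age) +
    unname(truth$beta_going[as.character(covariates$going5)]) +
    unname(truth$beta_year[yr]) +
    unname(truth$beta_off[as.character(covariates$off_band)]) +
    truth$beta_prev * prev
  for (re in c("horse_id", "meet_id")) {
    if (!is.null(covariates[[re]])) {
      b <- if (re == "horse_id") truth$b_horse else truth$b_meet
      idx <- match(as.character(covariates[[re]]), names(b))
      if (strict && any(is.na(idx))) {
        stop("true_linear_predictor: unknown ", re, call. = FALSE)
      }
      eta <- eta + ifelse(is.na(idx), 0, b[idx])
    }
  }
  unname(eta)
}
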