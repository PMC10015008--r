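test_that("generator is reproducible from its seed", {
  cfg <- generator_config(n_runners = 3000L, n_horses = 300L, n_courses = 4L,
                          prevalence_target = 0.02, seed = 5L)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$runners, b$runners)
  expect_identical(a$weather, b$weather)
  expect_identical(a$truth$eta, b$truth$eta)
})

test_that("simulated weather has a seasonal cycle and tmax-rh anticorrelation", {
  cfg <- generator_config(n_runners = 1000L, n_horses = 100L, n_courses = 3L,
                          date_start = as.Date("2015-01-01"),
                          date_end = as.Date("2016-12-31"), seed = 8L)
  w <- simulate_weather(cfg)
  m <- as.integer(format(w$date, "%m"))
  expect_gt(mean(w$tmax_c[m == 7]), mean(w$tmax_c[m == 1]) + 5)
  expect_lt(cor(w$tmax_c, w$rh_pct), -0.2)
  expect_between(w$rh_pct, 20, 100)
  expect_between(w$tmax_c, -5, 38)
  expect_false(any(duplicated(paste(w$course_id, w$date))))
})

test_that("null generator reduces to iid Bernoulli at the target rate", {
  tt <- list(distance_yards = NULL, wbgt_c = NULL, prev5_c = NULL, age = NULL)
  cfg <- generator_config(n_runners = 40000L, n_horses = 3000L, n_courses = 5L,
                          prevalence_target = 0.1, smooth_truths = tt,
                          beta_prev = 0, beta_off = c(pre5pm = 0, post5pm = 0),
                          beta_going = c(firm = 0, good = 0, soft = 0,
                                         heavy = 0, standard = 0),
                          beta_year = setNames(rep(0, 9), 2010:2018),
                          sigma_horse = 0, sigma_meet = 0, seed = 31L)
  sim <- simulate_population(cfg)
  n <- nrow(sim$runners)
  p <- mean(sim$runners$ehi)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # and the intercept alone carries the rate
  expect_equal(sim$truth$alpha, qlogis(0.1), tolerance = 0.02)
})

test_that("realised events fall in the central binomial interval at study scale", {
  cfg <- generator_config(seed = 19L)
  sim <- memo("default_sim_19", simulate_population(cfg))
  n <- nrow(sim$runners)
  ev <- sum(sim$runners$ehi)
  ci <- qbinom(c(0.005, 0.995), n, cfg$prevalence_target)
  expect_gte(ev, ci[1])
  expect_lte(ev, ci[2])
  # repeated runs per horse and meet clustering are present
  expect_gt(mean(table(sim$runners$horse_id)), 5)
  expect_gt(mean(table(sim$runners$meet_id)), 20)
})

test_that("stored truth reproduces the simulated linear predictor exactly", {
  sim <- small_sim()
  r <- sim$runners
  idx <- seq(1, nrow(r), by = 37)
  w <- sim$weather
  cov <- data.frame(
    distance_yards = r$distance_yards[idx],
    wbgt_c = {
      k <- match(paste(r$course_id[idx], r$date[idx]),
                 paste(w$course_id, w$date))
      wbgt_from_weather(w$tmax_c[k], w$rh_pct[k])
    },
    prev5_c = preceding_average(w, r$course_id[idx], r$date[idx]),
    age = r$age[idx],
    going5 = as.character(collapse_going(
      ifelse(r$going_raw[idx] == "fast", "standard", r$going_raw[idx]))),
    year = format(r$date[idx], "%Y"),
    off_band = as.character(derive_off_band(r$off_time[idx])),
    prev_incident = sim$truth$prev_flag[idx],
    horse_id = r$horse_id[idx],
    meet_id = r$meet_id[idx],
    stringsAsFactors = FALSE)
  eta <- true_linear_predictor(sim$truth, cov)
  expect_equal(eta, sim$truth$eta[idx], tolerance = 1e-10)

  # toggling the previous-incident state shifts the log-odds by beta_prev
  cov2 <- cov; cov2$prev_incident <- 1 - cov$prev_incident
  expect_equal(true_linear_predictor(sim$truth, cov2) - eta,
               sim$truth$beta_prev * (1 - 2 * cov$prev_incident),
               tolerance = 1e-10)

  # a WBGT change moves eta by the truth-table increment
  cov3 <- cov; cov3$wbgt_c <- cov$wbgt_c + 2
  st <- sim$truth$smooth_truths$wbgt_c
  expect_equal(true_linear_predictor(sim$truth, cov3) - eta,
               approx(st$x, st$f, cov3$wbgt_c)$y - approx(st$x, st$f, cov$wbgt_c)$y,
               tolerance = 1e-10)

  # out-of-support covariates are refused
  cov4 <- cov; cov4$age[1] <- 40
  expect_error(true_linear_predictor(sim$truth, cov4), "support")
  cov5 <- cov; cov5$horse_id[1] <- "nobody"
  expect_error(true_linear_predictor(sim$truth, cov5), "unknown")
})

test_that("ground-truth odds ratios are recomputable from the truth object", {
  sim <- small_sim()
  st <- sim$truth$smooth_truths
  f <- function(tab, x) approx(tab$x, tab$f, x)$y
  expect_equal(exp(f(st$wbgt_c, 30) - f(st$wbgt_c, 20)), 10.14, tolerance = 1e-6)
  expect_equal(exp(f(st$distance_yards, 3520) - f(st$distance_yards, 1760)),
               5.66, tolerance = 1e-6)
  expect_equal(exp(f(st$prev5_c, 25) - f(st$prev5_c, 15)), 0.33, tolerance = 1e-6)
  expect_equal(exp(f(st$age, 4) - f(st$age, 2)), 1.34, tolerance = 1e-6)
  expect_equal(exp(f(st$age, 6) - f(st$age, 4)), 0.82, tolerance = 1e-6)
  expect_equal(exp(sim$truth$beta_prev), 18.59, tolerance = 1e-6)
})

test_that("generated records satisfy the record invariants", {
  sim <- small_sim()
  r <- sim$runners
  expect_false(any(duplicated(paste(r$horse_id, r$race_id))))
  expect_false(any(duplicated(paste(r$horse_id, r$date))))
  expect_true(all(r$distance_yards > 0))
  expect_true(all(r$age >= 1))
  expect_true(all(r$ehi %in% 0:1))
  # validates against the CSV contract as-is
  expect_silent(validate_runners(r))
  expect_silent(validate_weather(sim$weather))
})
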