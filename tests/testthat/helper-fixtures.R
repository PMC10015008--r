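# Shared fixtures, built in code. Expensive simulations are memoised so
# several test files can reuse one object.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Minimal valid runner table (2 horses, 3 runs, one EHI).
tiny_runners <- function() {
  data.frame(
    horse_id = c("H1", "H1", "H2"),
    meet_id = c("M1", "M2", "M1"),
    course_id = c("C1", "C2", "C1"),
    race_id = c("R1", "R2", "R3"),
    date = as.Date(c("2016-07-01", "2016-07-10", "2016-07-01")),
    off_time = c("14:30", "17:00", "15:05"),
    distance_yards = c(1760, 3520, 2200),
    race_type = c("flat", "jump", "flat"),
    going_raw = c("good", "soft", "good"),
    age = c(4L, 4L, 6L),
    sex = c("gelding", "gelding", "filly"),
    ehi = c(0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

# Weather covering the tiny runners' course-dates plus preceding windows.
tiny_weather <- function() {
  grid <- expand.grid(course_id = c("C1", "C2"),
                      date = seq(as.Date("2016-06-20"), as.Date("2016-07-12"),
                                 by = "day"), stringsAsFactors = FALSE)
  grid$tmax_c <- 20 + 2 * sin(as.numeric(grid$date) / 3) +
    ifelse(grid$course_id == "C2", 1, 0)
  grid$rh_pct <- 65
  grid
}

# Small simulated population shared across gamm/selection/effects tests:
# ~12k runners at 1% prevalence with compact horse/meet clustering.
small_sim <- function() {
  memo("small_sim", {
    cfg <- generator_config(n_runners = 12000L, n_horses = 900L,
                            n_courses = 8L, prevalence_target = 0.01,
                            runners_per_meet = 60, seed = 901L)
    simulate_population(cfg)
  })
}

small_frame <- function() {
  memo("small_frame", {
    sim <- small_sim()
    build_model_frame(sim$runners, sim$weather)
  })
}

# A fitted model on the down-sampled small frame (full factor set).
small_fit <- function() {
  memo("small_fit", {
    ds <- downsample_controls(small_frame(), ratio = 10, seed = 77L)
    spec <- ehi_model_spec(
      smooths = c(age = 6, distance_yards = 8, wbgt_c = 8, prev5_c = 8),
      factors = c("going5", "prev_incident", "year", "off_band"))
    # sparse year/going cells at this fixture size can sit near separation;
    # the resulting magnitude warning is expected and harmless here
    suppressWarnings(fit_gamm(ds, spec))
  })
}

expect_between <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              info = sprintf("value %s not in [%s, %s]",
                             paste(signif(x, 4), collapse = ","), lo, hi))
}
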