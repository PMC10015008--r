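test_that("smooth interval ORs are exact on the log scale", {
  fit <- small_fit()
  # null contrast
  o <- smooth_interval_or(fit, "wbgt_c", 18, 18)
  expect_equal(o$or, 1)
  expect_true(o$ci_low <= 1 && o$ci_high >= 1)
  # telescoping: OR(a,b) * OR(b,c) = OR(a,c)
  oab <- smooth_interval_or(fit, "wbgt_c", 10, 18)
  obc <- smooth_interval_or(fit, "wbgt_c", 18, 26)
  oac <- smooth_interval_or(fit, "wbgt_c", 10, 26)
  expect_equal(oab$log_or + obc$log_or, oac$log_or, tolerance = 1e-10)
  # exp identity and interval ordering
  expect_equal(oab$or, exp(oab$log_or))
  expect_true(oab$ci_low <= oab$or && oab$or <= oab$ci_high)
  # outside the training range is refused
  expect_error(smooth_interval_or(fit, "wbgt_c", 10, 1e3), "training range")
  expect_error(smooth_interval_or(fit, "going5", 1, 2), "not a smooth")
})

test_that("pairwise ORs equal exponentiated coefficient differences", {
  fit <- small_fit()
  pc <- pairwise_category_or(fit, "going5")
  levs <- fit$builders$xlevels$going5
  expect_equal(nrow(pc), choose(length(levs), 2))
  # treatment coding: OR(A/B) = exp(beta_A - beta_B), reference beta = 0
  b <- setNames(rep(0, length(levs)), levs)
  cols <- which(fit$builders$par_assign ==
                  match("going5", fit$spec$factors))
  b[levs[-1]] <- fit$beta[cols]
  for (i in seq_len(nrow(pc))) {
    ab <- strsplit(pc$comparison[i], "/", fixed = TRUE)[[1]]
    expect_equal(pc$or[i], exp(b[ab[1]] - b[ab[2]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_true(all(pc$ci_low <= pc$or & pc$or <= pc$ci_high))
  expect_true(all(pc$or > 0))
  expect_between(pc$p_adjusted, 0, 1)
})

test_that("single-contrast families reduce to the plain two-sided p-value", {
  fit <- small_fit()
  pc <- pairwise_category_or(fit, "prev_incident")
  expect_equal(nrow(pc), 1)
  expect_equal(pc$p_adjusted, 2 * pnorm(-abs(pc$z)), tolerance = 1e-12)
})

test_that("adjusted p-values dominate their unadjusted counterparts", {
  fit <- small_fit()
  pc <- pairwise_category_or(fit, "year")
  p_raw <- 2 * pnorm(-abs(pc$z))
  expect_true(all(pc$p_adjusted >= p_raw - 1e-6))
})

test_that("pairwise ORs are invariant to the factor reference level", {
  sim <- small_sim()
  ds <- downsample_controls(small_frame(), ratio = 10, seed = 78L)
  spec <- ehi_model_spec(smooths = c(wbgt_c = 6), factors = "going5",
                         randoms = character(0))
  f1 <- suppressWarnings(fit_gamm(ds, spec))
  ds2 <- ds
  ds2$going5 <- stats::relevel(ds2$going5, "soft")
  f2 <- suppressWarnings(fit_gamm(ds2, spec))
  a <- pairwise_category_or(f1, "going5")
  b <- pairwise_category_or(f2, "going5")
  key <- function(d) {
    s <- strsplit(d$comparison, "/", fixed = TRUE)
    lor <- log(d$or)
    flip <- vapply(s, function(x) x[1] > x[2], logical(1))
    data.frame(cmp = vapply(s, function(x) paste(sort(x), collapse = "/"),
                            character(1)),
               lor = ifelse(flip, -lor, lor))
  }
  ka <- key(a); kb <- key(b)
  kb <- kb[match(ka$cmp, kb$cmp), ]
  # levels with no cases in the fixture give information-free contrasts
  # (|log OR| in the tens, SE thousands); invariance is asserted on the
  # identified contrasts
  ident <- abs(ka$lor) < 8
  expect_gt(sum(ident), 0)
  expect_equal(ka$lor[ident], kb$lor[ident], tolerance = 1e-6)
})

test_that("probability surfaces respect additive structure and adjustment", {
  fit <- small_fit()
  r <- fit$builders$ranges$distance_yards
  grid <- list(distance_yards = seq(r[1], r[2], length.out = 12),
               prev_incident = c("no", "yes"))
  surf <- probability_surface(fit, grid = grid)
  expect_equal(nrow(surf), 24)
  expect_equal(surf$prob_abs,
               adjust_probability(surf$prob_model, fit$sampling))
  # previous-incident surface lies uniformly above when its log-odds are +
  cols <- which(fit$builders$par_assign ==
                  match("prev_incident", fit$spec$factors))
  stopifnot(fit$beta[cols] > 0)
  w <- reshape(surf[, c("distance_yards", "prev_incident", "prob_abs")],
               idvar = "distance_yards", timevar = "prev_incident",
               direction = "wide")
  expect_true(all(w$prob_abs.yes > w$prob_abs.no))
  # out-of-range and unknown grid values are refused
  expect_error(probability_surface(fit, grid = list(distance_yards = 1e7)),
               "training range")
  expect_error(probability_surface(fit, grid = list(going5 = "boggy")),
               "unknown level")
})

test_that("surface along a monotone fitted smooth is monotone", {
  set.seed(23)
  n <- 4000
  d <- data.frame(x = runif(n, 0, 10))
  d$ehi <- rbinom(n, 1, plogis(-3 + 0.4 * d$x))
  attr(d, "sampling") <- list(q = mean(d$ehi), pi = mean(d$ehi))
  spec <- ehi_model_spec(smooths = c(x = 8), factors = character(0),
                         randoms = character(0))
  fit <- fit_gamm(d, spec)
  surf <- probability_surface(fit, sampling = list(q = 0.1, pi = 0.01),
                              grid = list(x = seq(0.5, 9.5, length.out = 25)))
  expect_true(all(diff(surf$prob_abs) > -1e-9))
})
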