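test_that("down-sampling keeps all cases at the requested control ratio", {
  fr <- data.frame(ehi = c(rep(1L, 659), rep(0L, 70000)))
  ds <- downsample_controls(fr, ratio = 10, seed = 1)
  expect_equal(nrow(ds), 7249)  # 659 cases + 6590 controls
  expect_equal(sum(ds$ehi), 659)
  s <- attr(ds, "sampling")
  expect_equal(s$q, 659 / 7249)
  expect_equal(s$pi, 659 / 70659)

  fr <- data.frame(ehi = c(rep(1L, 5), rep(0L, 10)))
  ds <- downsample_controls(fr, ratio = 2, seed = 1)
  expect_equal(nrow(ds), 15)
  expect_equal(sum(ds$ehi), 5)
  expect_warning(ds2 <- downsample_controls(fr, ratio = 100),
                 "fewer controls")
  expect_equal(nrow(ds2), 15)
  expect_error(downsample_controls(data.frame(ehi = c(0L, 0L)), 2), "no cases")
})

test_that("class adjustment is the exact odds-scale prior correction", {
  s <- list(q = 0.1, pi = 0.001)
  expect_equal(adjust_probability(0.5, s), 0.008929, tolerance = 1e-6 / 0.0089)
  expect_equal(adjust_probability(c(0, 1), s), c(0, 1))
  # identity when no down-sampling happened
  expect_equal(adjust_probability(seq(0, 1, 0.1), list(q = 0.3, pi = 0.3)),
               seq(0, 1, 0.1))
  # strictly increasing
  p <- seq(0.001, 0.999, length.out = 50)
  expect_true(all(diff(adjust_probability(p, s)) > 0))
  # composing with the inverse correction restores the input
  inv <- list(q = s$pi, pi = s$q)
  expect_equal(adjust_probability(adjust_probability(p, s), inv), p,
               tolerance = 1e-12)
})

test_that("intercept-only fit reduces to the binomial GLM limit", {
  set.seed(42)
  fr <- data.frame(ehi = rbinom(4000, 1, 0.07))
  spec <- ehi_model_spec(smooths = c(), factors = character(0),
                         randoms = character(0))
  fit <- fit_gamm(fr, spec)
  expect_equal(unname(fit$beta[1]), qlogis(mean(fr$ehi)), tolerance = 1e-6)
  expect_equal(mean(fit$fitted), mean(fr$ehi), tolerance = 1e-8)
})

test_that("a single linear effect is recovered within 2 SE of a GLM oracle", {
  set.seed(7)
  n <- 6000
  d <- data.frame(x = runif(n, 0, 10))
  d$ehi <- rbinom(n, 1, plogis(-2.5 + 0.35 * d$x))
  spec <- ehi_model_spec(smooths = c(x = 10), factors = character(0),
                         randoms = character(0))
  fit <- fit_gamm(d, spec)
  # oracle: unpenalized logistic regression on the same data
  gl <- glm(ehi ~ x, binomial, d)
  slope_hat <- smooth_interval_or(fit, "x", 2, 8)
  oracle <- 6 * coef(gl)["x"]
  oracle_se <- 6 * summary(gl)$coefficients["x", 2]
  expect_lt(abs(slope_hat$log_or - oracle),
            2 * sqrt(oracle_se^2 + slope_hat$se^2))
  # fitted probabilities average to the observed rate (intercept score eq.)
  expect_equal(mean(fit$fitted), mean(d$ehi), tolerance = 1e-6)
})

test_that("a pure-noise smooth is shrunk towards zero degrees of freedom", {
  set.seed(11)
  n <- 5000
  d <- data.frame(x = runif(n, 0, 10), z = runif(n, 0, 1))
  d$ehi <- rbinom(n, 1, plogis(-2 + 0.3 * d$x))
  spec <- ehi_model_spec(smooths = c(x = 10, z = 10), factors = character(0),
                         randoms = character(0))
  fit <- fit_gamm(d, spec)
  expect_lt(fit$edf["z"], 0.6)
  expect_gt(fit$edf["x"], 0.8)
  # the fitted z-contribution is essentially flat
  or_z <- smooth_interval_or(fit, "z", 0.1, 0.9)
  expect_lt(abs(or_z$log_or), 0.1)
})

test_that("prediction honours random-effect semantics and clamping", {
  fit <- small_fit()
  fr <- small_frame()
  nd <- fr[1:50, ]
  p_in <- predict_probability(fit, nd)
  expect_between(p_in, 0, 1)
  # unseen groups get zero random intercepts
  nd2 <- nd
  nd2$horse_id <- "UNSEEN"; nd2$meet_id <- "UNSEEN"
  expect_equal(predict_probability(fit, nd2),
               predict_probability(fit, nd, include_random = FALSE))
  # unseen factor level errors
  nd3 <- nd; nd3$going5 <- factor("boggy")
  expect_error(predict_probability(fit, nd3), "unseen level")
  # out-of-range smooth values clamp to the endpoint prediction
  nd4 <- nd[1, ]; nd4$distance_yards <- 1e6
  nd5 <- nd[1, ]; nd5$distance_yards <- max(small_frame()$distance_yards)
  expect_warning(p4 <- predict_probability(fit, nd4), "clamped")
  expect_equal(p4, predict_probability(fit, nd5))
})

test_that("in-sample predictions reproduce fitted values", {
  set.seed(13)
  n <- 2000
  d <- data.frame(x = runif(n), g = factor(sample(letters[1:10], n, TRUE)))
  d$ehi <- rbinom(n, 1, plogis(-1 + d$x))
  spec <- ehi_model_spec(smooths = c(x = 6), factors = character(0),
                         randoms = "g")
  fit <- fit_gamm(d, spec)
  expect_equal(predict_probability(fit, d, include_random = TRUE),
               unname(fit$fitted), tolerance = 1e-8)
})

test_that("sending all smoothing parameters to infinity removes the smooths", {
  set.seed(9)
  n <- 3000
  d <- data.frame(x = runif(n, 0, 10))
  d$ehi <- rbinom(n, 1, plogis(-2 + 0.3 * d$x))
  spec <- ehi_model_spec(smooths = c(x = 10), factors = character(0),
                         randoms = character(0))
  fit <- fit_gamm(d, spec, lambda_fixed = c(x = 1e10))
  grid <- data.frame(x = seq(0.5, 9.5, length.out = 20))
  eta <- predict_probability(fit, grid, type = "link")
  expect_lt(max(eta) - min(eta), 1e-3)
  expect_lt(fit$edf["x"], 0.01)
})

test_that("fit refuses non-binary responses and single-level factors", {
  d <- data.frame(ehi = c(0, 1, 2, 0), f = factor(c("a", "a", "a", "a")))
  spec <- ehi_model_spec(smooths = c(), factors = "f", randoms = character(0))
  expect_error(fit_gamm(d, spec), "binary")
  d$ehi <- c(0, 1, 1, 0)
  expect_error(fit_gamm(d, spec), "single observed level")
})
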