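test_that("Brier score matches hand values and a naive loop oracle", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(c(1, 0), c(0, 1)), 1)
  expect_equal(brier_score(c(0.9, 0.1), c(1, 0)), 0.01)
  expect_error(brier_score(c(0.5), c(1, 0)), "length")
  set.seed(4)
  f <- runif(500); o <- rbinom(500, 1, 0.3)
  loop <- 0
  for (i in seq_along(f)) loop <- loop + (f[i] - o[i])^2
  expect_equal(brier_score(f, o), loop / 500, tolerance = 1e-13)
})

test_that("reference score is the outcome-rate variance", {
  expect_equal(brier_max(0), 0)
  expect_equal(brier_max(0.1), 0.09)
  expect_equal(brier_max(0.5), 0.25)
  p <- runif(20)
  expect_equal(brier_max(p), p * (1 - p))
})

test_that("scaled Brier variants match hand values and decrease in BS", {
  expect_equal(scaled_brier(1, 0.09, "as_printed"), 0)
  expect_equal(scaled_brier(0.01, 0.09, "as_printed"), 11.0)
  expect_equal(scaled_brier(0.01, 0.09, "complement_ratio"), 0.8889,
               tolerance = 1e-4)
  bs <- seq(0.001, 0.9, length.out = 30)
  expect_true(all(diff(scaled_brier(bs, 0.09, "as_printed")) < 0))
  expect_true(all(diff(scaled_brier(bs, 0.09, "complement_ratio")) < 0))
  expect_error(scaled_brier(0.1, 0), "BS_max")
})

test_that("fold partition is balanced, exhaustive and seed-stable", {
  f <- kfold_partition(10, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(f, kfold_partition(10, 5, seed = 3))
  f2 <- kfold_partition(103, 5, seed = 9)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_setequal(unique(f2), 1:5)
  expect_error(kfold_partition(3, 5), "n >= k")
})

test_that("cross-validated Brier of the null model matches the analytic value", {
  set.seed(21)
  pi0 <- 0.05
  fr <- data.frame(ehi = rbinom(6000, 1, pi0))
  spec <- ehi_model_spec(smooths = c(), factors = character(0),
                         randoms = character(0))
  config <- pipeline_config(downsample_ratio = 10, seed = 2)
  cv <- cv_score(fr, spec, config)
  # constant forecast at pi -> BS = pi(1-pi)
  expect_equal(cv$mean_bs, pi0 * (1 - pi0), tolerance = 0.1)
  expect_equal(nrow(cv$folds), 5)
  expect_gt(cv$sd_bs, 0)
  # every row appears in exactly one test fold
  expect_setequal(cv$pred$row, seq_len(nrow(fr)))
})

test_that("test folds influence only their own scores, never the fit", {
  sim <- small_sim()
  fr <- small_frame()
  spec <- ehi_model_spec(smooths = c(wbgt_c = 6),
                         factors = "prev_incident", randoms = character(0))
  config <- pipeline_config(k_folds = 2, seed = 33)
  folds <- kfold_partition(nrow(fr), 2, seed = 44)
  cv1 <- cv_score(fr, spec, config, folds = folds)
  # permute the responses of fold-1 rows only: fold-1 predictions (made by a
  # model trained on fold 2) must be unchanged, while fold-1's score changes
  fr2 <- fr
  i1 <- which(folds == 1)
  fr2$ehi[i1] <- with_local_seed(5, sample(fr2$ehi[i1]))
  cv2 <- cv_score(fr2, spec, config, folds = folds)
  expect_equal(cv1$pred$prob_abs[cv1$pred$fold == 1],
               cv2$pred$prob_abs[cv2$pred$fold == 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv1$folds$bs[1], cv2$folds$bs[1])))
})

test_that("oracle forecasts score no worse than the fitted model", {
  sim <- small_sim()
  fr <- small_frame()
  spec <- ehi_model_spec(smooths = c(wbgt_c = 6, distance_yards = 6),
                         factors = "prev_incident", randoms = character(0))
  config <- pipeline_config(seed = 61)
  cv <- cv_score(fr, spec, config)
  # true event probabilities from the generator, same rows
  cov <- fr
  cov$year <- as.character(fr$year)
  cov$prev_incident <- as.integer(fr$prev_incident == "yes")
  eta <- true_linear_predictor(sim$truth, cov, strict = FALSE)
  bs_oracle <- brier_score(plogis(eta)[cv$pred$row], cv$pred$outcome)
  expect_lte(bs_oracle, cv$mean_bs + 1e-4)
})

test_that("backward selection drops a null term and keeps a strong one", {
  set.seed(71)
  n <- 4000
  d <- data.frame(
    strong = factor(sample(c("lo", "hi"), n, TRUE)),
    noise = factor(sample(letters[1:3], n, TRUE)))
  d$ehi <- rbinom(n, 1, plogis(-2.5 + 1.6 * (d$strong == "hi")))
  spec <- ehi_model_spec(smooths = c(), factors = c("strong", "noise"),
                         randoms = character(0))
  config <- pipeline_config(seed = 81, downsample_ratio = 3)
  sel <- backward_select(d, spec, config)
  expect_true("strong" %in% sel$spec$factors)
  expect_false("noise" %in% sel$spec$factors)
  # ledger bookkeeping: every evaluated model recorded, removals unique
  expect_true(all(c("incumbent", "evaluated") %in% sel$ledger$decision))
  removed <- sel$ledger$removed[sel$ledger$decision == "removed"]
  expect_false(anyDuplicated(removed) > 0)
  # with tolerance 0 a strictly improving removal is still accepted
  config0 <- pipeline_config(seed = 81, selection_tolerance = 0,
                             downsample_ratio = 3)
  sel0 <- backward_select(d, spec, config0)
  expect_true("strong" %in% sel0$spec$factors)
})
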