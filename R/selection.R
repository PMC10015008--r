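# Cross-validated Brier scoring and backward stepwise variable selection.
# Candidate models are compared on the scaled Brier score of class-adjusted
# test-fold predictions; test folds are never down-sampled, so they reflect
# the population incidence.

#' Brier score of probabilistic forecasts
#'
#' Mean squared difference between forecast probabilities and binary
#' outcomes: `BS = (1/N) * sum((f_t - o_t)^2)`, in `[0, 1]`, lower is better.
#'
#' @param f Forecast probabilities in `[0, 1]`.
#' @param o Binary outcomes (0/1), same length as `f`.
#' @return The Brier score.
#' @export
brier_score <- function(f, o) {
  if (length(f) != length(o)) stop("brier_score: length mismatch", call. = FALSE)
  if (!length(f)) stop("brier_score: empty input", call. = FALSE)
  stopifnot(all(f >= 0 & f <= 1), all(o %in% c(0, 1)))
  mean((f - o)^2)
}

#' Maximum (reference) Brier score at a given outcome rate
#'
#' `BS_max = mean_p (1 - mean_p)^2 + (1 - mean_p) mean_p^2`, which simplifies
#' to `mean_p (1 - mean_p)`: the Brier score of the constant forecast at the
#' outcome rate. Used to scale scores so folds with different incidence are
#' comparable.
#'
#' @param mean_p Average outcome probability (observed outcome proportion).
#' @return The reference score.
#' @export
brier_max <- function(mean_p) {
  stopifnot(all(mean_p >= 0 & mean_p <= 1))
  mean_p * (1 - mean_p)^2 + (1 - mean_p) * mean_p^2
}

#' Scaled Brier score
#'
#' Two scalings are available, both strictly decreasing in `BS` (higher is
#' better): `"complement_ratio"`, the standard Brier skill score
#' `1 - BS/BS_max` relative to the constant forecast at the outcome rate; and
#' `"as_printed"`, the ratio `(1 - BS)/BS_max`. At rare-event incidences the
#' two differ by orders of magnitude; only the skill-score form lives on a
#' 0-1 scale (reported as a percentage when multiplied by 100), which is why
#' it is the default.
#'
#' @param bs Brier score.
#' @param bs_max Reference score from [brier_max()]; must be > 0.
#' @param variant `"complement_ratio"` (default) or `"as_printed"`.
#' @return The scaled score (unitless; multiply by 100 for percent).
#' @export
scaled_brier <- function(bs, bs_max,
                         variant = c("complement_ratio", "as_printed")) {
  variant <- match.arg(variant)
  if (any(bs_max <= 0)) {
    stop("scaled_brier: undefined score, BS_max = 0 (fold without both classes)",
         call. = FALSE)
  }
  switch(variant,
         complement_ratio = 1 - bs / bs_max,
         as_printed = (1 - bs) / bs_max)
}

#' Random k-fold partition
#'
#' Uniformly random row-level fold assignment with fold sizes differing by at
#' most one; deterministic given `seed`.
#'
#' @param n Number of rows (or a data frame).
#' @param k Number of folds (>= 2).
#' @param seed Optional seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_partition <- function(n, k, seed = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(k >= 2, n >= k)
  with_local_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated Brier assessment of a candidate model
#'
#' For each fold: the training portion (all other folds) is down-sampled to
#' the configured control:case ratio, the model is fitted, and the untouched
#' test fold is predicted (random intercepts of unseen horses/meets are 0).
#' Predictions are put on the absolute scale with that training split's class
#' adjustment, then scored with the Brier score and its scaled version using
#' the test fold's observed outcome proportion. Test folds are never
#' down-sampled. A fold without any case yields `BS_max = 0`; a warning is
#' issued and the scaled score for that fold is `NA`.
#'
#' @param frame Analysis-ready model frame.
#' @param spec An [ehi_model_spec()].
#' @param config A [pipeline_config()] (uses `k_folds`, `downsample_ratio`,
#'   `brier_scale_variant`, `seed`, `cv_control`).
#' @param folds Optional precomputed fold labels (so competing models can be
#'   scored on the identical partition).
#' @param lambda_init Optional named smoothing-parameter warm start for the
#'   first fold's fit (later folds warm-start from the previous fold).
#' @return An `ehi_cv` list: `folds` (per-fold data frame with `n`, `cases`,
#'   `bs`, `bs_max`, `bs_scale_pct`), `mean_bs`, `sd_bs`, `mean_scaled_pct`,
#'   `sd_scaled_pct`, and the per-fold predictions (`pred`) with row indices.
#' @export
cv_score <- function(frame, spec, config, folds = NULL, lambda_init = NULL) {
  k <- config$k_folds
  if (is.null(folds)) {
    folds <- kfold_partition(nrow(frame), k, seed = config$seed)
  }
  stopifnot(length(folds) == nrow(frame))
  res <- vector("list", k)
  preds <- vector("list", k)
  lambda_warm <- lambda_init
  for (i in seq_len(k)) {
    test <- frame[folds == i, , drop = FALSE]
    train <- frame[folds != i, , drop = FALSE]
    ds <- downsample_controls(train, ratio = config$downsample_ratio,
                              seed = config$seed * 131L + i,
                              response = spec$response)
    fit <- tryCatch(
      fit_gamm(ds, spec, lambda_init = lambda_warm, control = config$cv_control),
      error = function(e) stop("cv_score: fold ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    lambda_warm <- fit$lambda
    p_model <- suppressWarnings(
      predict_probability(fit, test, include_random = TRUE))
    p_abs <- adjust_probability(p_model, fit$sampling)
    o <- test[[spec$response]]
    bs <- brier_score(p_abs, o)
    bmax <- brier_max(mean(o))
    if (bmax == 0) {
      warning("cv_score: fold ", i, " contains a single outcome class")
      sc <- NA_real_
    } else {
      sc <- scaled_brier(bs, bmax, config$brier_scale_variant)
    }
    res[[i]] <- data.frame(fold = i, n = nrow(test), cases = sum(o),
                           bs = bs, bs_max = bmax, bs_scale_pct = 100 * sc)
    preds[[i]] <- data.frame(row = which(folds == i), fold = i,
                             prob_abs = p_abs, outcome = o)
  }
  tab <- do.call(rbind, res)
  out <- list(lambda_last = lambda_warm,
              folds = tab,
              mean_bs = mean(tab$bs), sd_bs = sd(tab$bs),
              mean_scaled_pct = mean(tab$bs_scale_pct, na.rm = TRUE),
              sd_scaled_pct = sd(tab$bs_scale_pct, na.rm = TRUE),
              pred = do.call(rbind, preds),
              fold_labels = folds)
  class(out) <- "ehi_cv"
  out
}

#' Backward stepwise selection under cross-validated scaled Brier score
#'
#' Starting from the maximal model, each removable term (smooths and
#' categorical fixed effects; random intercepts are never candidates) is
#' tentatively removed and the reduced model scored by [cv_score()] on one
#' fixed fold partition. The removal with the best mean scaled score is
#' accepted provided it is not worse than the incumbent by more than
#' `selection_tolerance` scaled-Brier percentage points (a removal that ties
#' or merely fails to improve the score does not justify keeping the term);
#' selection stops when no removal qualifies. The ledger records every model
#' evaluated.
#'
#' @inheritParams cv_score
#' @param full_spec The maximal [ehi_model_spec()].
#' @return A list: `spec` (selected model), `ledger` (data frame with one row
#'   per evaluated model: step, model label, removed term, mean/SD Brier,
#'   mean scaled %, delta vs incumbent, decision), `cv` (the selected
#'   model's `ehi_cv`).
#' @export
backward_select <- function(frame, full_spec, config) {
  folds <- kfold_partition(nrow(frame), config$k_folds,
                           seed = config$seed * 977L + 5L)
  ledger <- list()
  add_row <- function(step, spec, removed, cv, delta, decision) {
    ledger[[length(ledger) + 1]] <<- data.frame(
      step = step, model = spec_label(spec), removed = removed,
      mean_brier = cv$mean_bs, sd_brier = cv$sd_bs,
      mean_scaled_pct = cv$mean_scaled_pct, sd_scaled_pct = cv$sd_scaled_pct,
      delta_scaled = delta, decision = decision, stringsAsFactors = FALSE)
  }
  incumbent <- full_spec
  inc_cv <- cv_score(frame, incumbent, config, folds = folds)
  add_row(0L, incumbent, "", inc_cv, NA_real_, "incumbent")
  step <- 0L
  repeat {
    step <- step + 1L
    cands <- removable_terms(incumbent)
    if (!length(cands)) break
    best <- NULL
    for (term in cands) {
      spec_c <- drop_term(incumbent, term)
      cv_c <- cv_score(frame, spec_c, config, folds = folds,
                       lambda_init = inc_cv$lambda_last)
      delta <- cv_c$mean_scaled_pct - inc_cv$mean_scaled_pct
      add_row(step, spec_c, term, cv_c, delta, "evaluated")
      if (is.null(best) || cv_c$mean_scaled_pct > best$cv$mean_scaled_pct) {
        best <- list(term = term, spec = spec_c, cv = cv_c, delta = delta)
      }
    }
    if (best$delta >= -config$selection_tolerance) {
      incumbent <- best$spec
      inc_cv <- best$cv
      add_row(step, incumbent, best$term, best$cv, best$delta, "removed")
    } else {
      break
    }
  }
  list(spec = incumbent, ledger = do.call(rbind, ledger), cv = inc_cv)
}
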