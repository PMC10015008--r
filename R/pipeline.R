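# End-to-end pipeline driver: preprocess -> cross-validated backward
# selection -> final down-sampled fit -> odds-ratio effects -> ROC/G-mean
# classification, with one master seed from which every stochastic stage
# (fold assignment, down-sampling, trace probes) derives deterministically.

#' Pipeline configuration
#'
#' @param k_folds Cross-validation folds (>= 2; default 5).
#' @param knots Knots per smooth term (default 10; the fitted results vary
#'   only marginally across 10/40/80).
#' @param downsample_ratio Controls retained per case (default 10, raising
#'   the ~0.1% incidence to ~9% in the fitted data).
#' @param target_prevalence Optional true case fraction used for the class
#'   adjustment; by default the observed case fraction of the input data.
#' @param threshold_step G-mean threshold grid increment (default 0.01).
#' @param selection_tolerance Scaled-Brier slack (percentage points) within
#'   which a removal is still accepted (default 0.05).
#' @param seed Master seed.
#' @param brier_scale_variant `"complement_ratio"` (default) or
#'   `"as_printed"`; see [scaled_brier()].
#' @param cv_control [gamm_control()] used for the many cross-validation
#'   fits (slightly looser convergence for speed).
#' @param fit_control [gamm_control()] used for the final fit.
#' @return A validated list of class `ehi_pipeline_config`.
#' @export
pipeline_config <- function(k_folds = 5L, knots = 10L, downsample_ratio = 10,
                            target_prevalence = NULL, threshold_step = 0.01,
                            selection_tolerance = 0.05, seed = 1L,
                            brier_scale_variant = c("complement_ratio",
                                                    "as_printed"),
                            cv_control = gamm_control(efs_maxit = 12L,
                                                      efs_tol = 0.05),
                            fit_control = gamm_control()) {
  if (k_folds < 2) stop("pipeline_config: k_folds must be >= 2", call. = FALSE)
  if (threshold_step <= 0 || threshold_step > 0.5) {
    stop("pipeline_config: threshold_step must be in (0, 0.5]", call. = FALSE)
  }
  if (downsample_ratio < 1) {
    stop("pipeline_config: downsample_ratio must be >= 1", call. = FALSE)
  }
  structure(list(k_folds = as.integer(k_folds), knots = as.integer(knots),
                 downsample_ratio = downsample_ratio,
                 target_prevalence = target_prevalence,
                 threshold_step = threshold_step,
                 selection_tolerance = selection_tolerance,
                 seed = as.integer(seed),
                 brier_scale_variant = match.arg(brier_scale_variant),
                 cv_control = cv_control, fit_control = fit_control),
            class = "ehi_pipeline_config")
}

#' Run the full EHI risk-factor pipeline
#'
#' Orchestrates: reading/validating inputs, covariate derivation and
#' exclusion filtering, backward stepwise model selection under 5-fold
#' cross-validated scaled Brier scores, a final fit of the selected model on
#' down-sampled data, odds-ratio effect extraction, and cross-validated
#' ROC/G-mean classification assessment. All stages are reproducible from
#' `config$seed`; rerunning with the same inputs and seed yields an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @param runners Runner records: a path to `runners.csv` or a data frame.
#' @param weather Weather records: a path to `weather.csv` or a data frame.
#' @param out_dir Optional directory; if given, writes `report.json`,
#'   `selection_ledger.csv` and `effects.csv` there.
#' @param spec Maximal model specification (default: the full study model
#'   with `config$knots` knots per smooth).
#' @param quiet Suppress stage log messages?
#' @return The report, an `ehi_report` list (selected model, CV scores,
#'   odds ratios, ROC summary, exclusion log, seed provenance), invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(config, runners, weather, out_dir = NULL,
                         spec = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ehi_pipeline_config"))
  say <- function(...) if (!quiet) message("[ehirisk] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(spec)) {
    spec <- ehi_model_spec(smooths = c(age = config$knots,
                                       distance_yards = config$knots,
                                       wbgt_c = config$knots,
                                       prev5_c = config$knots))
  }

  say("stage load (seed ", config$seed, ")")
  runners <- stage("load", if (is.character(runners)) read_runners(runners)
                   else validate_runners(runners))
  weather <- stage("load", if (is.character(weather)) read_weather(weather)
                   else validate_weather(weather))

  say("stage preprocess: ", nrow(runners), " runners")
  frame <- stage("preprocess", build_model_frame(runners, weather))
  excl <- attr(frame, "exclusion_log")
  say("  retained ", nrow(frame), " rows (excluded: ",
      paste(names(excl), excl, sep = "=", collapse = ", "), ")")

  say("stage select: backward CV selection, k=", config$k_folds)
  sel <- stage("select", backward_select(frame, spec, config))
  say("  selected: ", spec_label(sel$spec))

  say("stage fit: final model on down-sampled data (ratio ",
      config$downsample_ratio, ")")
  ds <- stage("fit", downsample_controls(frame, ratio = config$downsample_ratio,
                                         seed = config$seed * 17L + 3L))
  if (!is.null(config$target_prevalence)) {
    s <- attr(ds, "sampling"); s$pi <- config$target_prevalence
    attr(ds, "sampling") <- s
  }
  fit <- stage("fit", fit_gamm(ds, sel$spec, control = config$fit_control))

  say("stage effects")
  effects <- stage("effects", {
    intervals <- list(distance_yards = c(1760, 3520), wbgt_c = c(20, 30),
                      prev5_c = c(15, 25), age = c(2, 4), age2 = c(4, 6))
    sm <- list()
    for (nm in names(intervals)) {
      v <- sub("[0-9]+$", "", nm)
      if (!v %in% names(sel$spec$smooths)) next
      r <- fit$builders$ranges[[v]]
      ab <- intervals[[nm]]
      if (ab[1] < r[1] || ab[2] > r[2]) next
      sm[[length(sm) + 1]] <- smooth_interval_or(fit, v, ab[1], ab[2])
    }
    ct <- lapply(sel$spec$factors, function(f) pairwise_category_or(fit, f))
    list(smooth = if (length(sm)) do.call(rbind, sm) else NULL,
         categorical = if (length(ct)) do.call(rbind, ct) else NULL)
  })

  say("stage classify: fold-wise ROC and G-mean thresholds")
  classify <- stage("classify", {
    pred <- sel$cv$pred
    fold_stats <- lapply(split(pred, pred$fold), function(d) {
      if (sum(d$outcome) == 0 || sum(d$outcome) == length(d$outcome)) {
        return(data.frame(fold = d$fold[1], auc = NA_real_,
                          threshold = NA_real_, gmean = NA_real_,
                          tp = NA, fp = NA, fn = NA, tn = NA))
      }
      roc <- roc_auc(d$prob_abs, d$outcome)
      thr <- gmean_threshold(d$prob_abs, d$outcome,
                             step = config$threshold_step)
      cm <- confusion(d$prob_abs, d$outcome, as.numeric(thr))
      data.frame(fold = d$fold[1], auc = roc$auc,
                 threshold = as.numeric(thr), gmean = attr(thr, "gmean"),
                 tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    })
    fold_stats <- do.call(rbind, fold_stats)
    thr_mean <- mean(fold_stats$threshold, na.rm = TRUE)
    pooled <- confusion(pred$prob_abs, pred$outcome, thr_mean)
    race <- race_level_summary(pred$prob_abs, pred$outcome,
                               frame$race_id[pred$row], thr_mean)
    list(per_fold = fold_stats,
         auc_mean = mean(fold_stats$auc, na.rm = TRUE),
         auc_sd = sd(fold_stats$auc, na.rm = TRUE),
         threshold_mean = thr_mean,
         threshold_sd = sd(fold_stats$threshold, na.rm = TRUE),
         confusion_median = lapply(
           fold_stats[c("tp", "fp", "fn", "tn")],
           function(x) stats::median(x, na.rm = TRUE)),
         confusion_pooled = pooled,
         race_level = race)
  })

  report <- list(
    seed = config$seed,
    n_input = nrow(runners), n_analysed = nrow(frame),
    prevalence = mean(frame$ehi),
    exclusion_log = as.list(excl),
    selected_model = spec_label(sel$spec),
    selection_ledger = sel$ledger,
    cv = list(mean_brier = sel$cv$mean_bs, sd_brier = sel$cv$sd_bs,
              mean_scaled_pct = sel$cv$mean_scaled_pct,
              sd_scaled_pct = sel$cv$sd_scaled_pct,
              per_fold = sel$cv$folds),
    effects = effects,
    classification = classify,
    sampling = fit$sampling,
    edf = as.list(fit$edf))
  class(report) <- "ehi_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    utils::write.csv(sel$ledger, file.path(out_dir, "selection_ledger.csv"),
                     row.names = FALSE)
    if (!is.null(effects$categorical)) {
      utils::write.csv(effects$categorical, file.path(out_dir, "effects.csv"),
                       row.names = FALSE)
    }
    say("report written to ", out_dir)
    return(invisible(report))
  }
  report
}
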