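Package: ehirisk
Title: Risk Factor Modelling and Prediction of Exertional Heat Illness in
    Racehorses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for modelling the risk of
    exertional heat illness (EHI) in Thoroughbred racehorses from runner-level
    race records and daily weather observations. Derives environmental
    covariates (an estimated wet bulb globe temperature index and the
    preceding five-day temperature average), applies the study exclusion
    filters, and fits rare-event binomial generalised additive mixed models
    with shrinkage splines and horse/race-meet random intercepts on
    case-control down-sampled data, using a sparse-matrix penalised IRLS
    fitter with Fellner-Schall REML smoothing-parameter updates. Model
    selection is by backward stepwise removal under 5-fold cross-validated
    scaled Brier scores; effects are reported as interval odds ratios for
    smooth terms and Tukey-adjusted pairwise marginal-mean odds ratios for
    categorical terms; absolute probabilities are recovered by a
    prior-correction class adjustment, and classification performance is
    summarised by ROC/AUC with a G-mean-optimised decision threshold. A
    synthetic race-population generator with known ground truth supports
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    mgcv,
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
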