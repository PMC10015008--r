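# ROC analysis, AUC, G-mean threshold optimisation, confusion matrices and
# race-level aggregation. The classification rule is prob >= threshold (ties
# classified positive).

.check_binary_scores <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop("probs and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop("labels must contain both classes", call. = FALSE)
  }
}

#' ROC curve and AUC
#'
#' Computes the ROC curve over all distinct score thresholds and the area
#' under it. The AUC equals the probability that a random case outscores a
#' random non-case, with tied scores contributing half (the Mann-Whitney
#' convention, identical to trapezoidal integration of the curve).
#'
#' @param probs Numeric scores (higher = more case-like).
#' @param labels Binary outcomes (0/1), both classes present.
#' @return An `ehi_roc` list: `thresholds` (decreasing), `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(probs, labels) {
  .check_binary_scores(probs, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(probs)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(probs, decreasing = TRUE)
  p_s <- probs[ord]; y_s <- labels[ord]
  last <- !duplicated(p_s, fromLast = TRUE)  # last row of each tied block
  tp <- cumsum(y_s)[last]
  fp <- cumsum(1 - y_s)[last]
  out <- list(thresholds = c(Inf, p_s[last]),
              tpr = c(0, tp / n1), fpr = c(0, fp / n0), auc = auc)
  class(out) <- "ehi_roc"
  out
}

.rate_at <- function(sorted_probs, t) {
  # count of sorted_probs >= t, via #(< t)
  length(sorted_probs) - findInterval(t, sorted_probs, left.open = TRUE)
}

#' G-mean-optimal decision threshold
#'
#' Evaluates `G = sqrt(TPR * (1 - FPR))` for the rule `prob >= t` on the grid
#' `t = 0, step, 2*step, ..., 1` and returns the smallest maximising
#' threshold (ties resolved toward sensitivity, appropriate for screening).
#'
#' @inheritParams roc_auc
#' @param step Grid increment (default 0.01).
#' @return The selected threshold, with attributes `gmean` (its G-mean) and
#'   `grid` (a data frame of threshold, tpr, fpr, gmean).
#' @export
gmean_threshold <- function(probs, labels, step = 0.01) {
  .check_binary_scores(probs, labels)
  stopifnot(step > 0, step <= 0.5)
  grid <- seq(0, 1, by = step)
  pos <- sort(probs[labels == 1]); neg <- sort(probs[labels == 0])
  tpr <- vapply(grid, function(t) .rate_at(pos, t), numeric(1)) / length(pos)
  fpr <- vapply(grid, function(t) .rate_at(neg, t), numeric(1)) / length(neg)
  g <- sqrt(tpr * (1 - fpr))
  i <- which.max(g)  # first (= smallest) maximiser
  structure(grid[i], gmean = g[i],
            grid = data.frame(threshold = grid, tpr = tpr, fpr = fpr, gmean = g))
}

#' Confusion matrix at a threshold
#'
#' Counts of the rule `prob >= threshold` against binary outcomes, with the
#' derived true positive rate, false positive rate and precision (positive
#' predictive value; `NA` when nothing is predicted positive).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold in `[0, 1]`.
#' @return A list: `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`, `precision`.
#' @export
confusion <- function(probs, labels, threshold) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)),
            threshold >= 0, threshold <= 1)
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Race-level classification summary
#'
#' Several horses run under the same conditions in a race but only a minority
#' present with EHI, so runner-level false positives can be reduced by asking
#' whether a *race* will contain an incident: a race is predicted positive
#' iff any of its runners has `prob >= threshold`, and observed positive iff
#' any runner has EHI.
#'
#' @inheritParams confusion
#' @param race_ids Race identifier per runner, aligned with `probs`.
#' @return As [confusion()], with counts over races.
#' @export
race_level_summary <- function(probs, labels, race_ids, threshold) {
  stopifnot(length(race_ids) == length(probs))
  pred <- rowsum(as.numeric(probs >= threshold), race_ids) > 0
  obs <- rowsum(as.numeric(labels), race_ids) > 0
  confusion(as.numeric(pred), as.numeric(obs), threshold = 1)
}
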