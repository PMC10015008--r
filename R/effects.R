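# Odds-ratio effect extraction from a fitted binomial GAMM. Odds ratios of a
# smooth term are not constant, so they are reported for stated intervals of
# the covariate; categorical terms are compared pairwise at marginal means
# (every other model term held at its mean fitted per-observation
# contribution, random effects at zero) with single-step multiplicity
# adjustment over the contrast family.

.focal_columns <- function(fit, term) {
  spec <- fit$spec
  if (!term %in% spec$factors) {
    stop("'", term, "' is not a categorical model term", call. = FALSE)
  }
  which(fit$builders$par_assign == match(term, spec$factors))
}

# Dense-design row for factor level `lev` of `term`, all other terms at their
# mean fitted contribution (xbar), random effects 0.
.level_row <- function(fit, term, lev, xbar) {
  cols <- .focal_columns(fit, term)
  levs <- fit$builders$xlevels[[term]]
  x <- xbar
  x[cols] <- as.numeric(levs[-1] == lev)  # treatment coding, reference = all 0
  x
}

#' Interval odds ratio from a fitted smooth term
#'
#' For a smooth `f`, the odds of EHI at covariate value `b` relative to value
#' `a`: `OR = exp(f(b) - f(a))`, with a delta-method standard error from the
#' coefficient covariance (`var = d' V d`, `d` the spline-basis difference
#' vector) and a 95% Wald interval on the log scale.
#'
#' @param fitted An `ehi_gamm` object.
#' @param term Name of a smooth covariate in the model.
#' @param a,b Covariate values (within the training range); the odds ratio
#'   compares `b` against `a`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row data frame: `comparison`, `or`, `ci_low`, `ci_high`,
#'   `z`, `log_or`, `se`.
#' @export
smooth_interval_or <- function(fitted, term, a, b, conf_level = 0.95) {
  stopifnot(inherits(fitted, "ehi_gamm"))
  blk <- fitted$layout$smooth_blocks[[term]]
  if (is.null(blk)) stop("'", term, "' is not a smooth model term", call. = FALSE)
  r <- fitted$builders$ranges[[term]]
  if (a < r[1] || a > r[2] || b < r[1] || b > r[2]) {
    stop("smooth_interval_or: interval endpoints outside the training range [",
         signif(r[1], 4), ", ", signif(r[2], 4), "]", call. = FALSE)
  }
  sm <- fitted$builders$smooths[[term]]
  nd <- data.frame(x = c(a, b)); names(nd) <- term
  B <- mgcv::PredictMat(sm, nd)
  d <- numeric(fitted$layout$p)
  d[blk$idx] <- B[2, ] - B[1, ]
  log_or <- sum(d * fitted$beta)
  se <- sqrt(.contrast_var(fitted, d))
  zq <- -qnorm((1 - conf_level) / 2)
  data.frame(comparison = sprintf("%s: %g vs %g", term, b, a),
             or = exp(log_or),
             ci_low = exp(log_or - zq * se),
             ci_high = exp(log_or + zq * se),
             z = if (se > 0) log_or / se else NA_real_,
             log_or = log_or, se = se,
             stringsAsFactors = FALSE)
}

#' Pairwise marginal-mean odds ratios for a categorical term
#'
#' Marginal means are formed by holding all model terms other than the one of
#' interest at their mean fitted per-observation contribution over the
#' training data (random effects at zero) and varying the focal factor level;
#' every pair of levels is then compared on the log-odds scale. P-values are
#' adjusted for the family of all `k(k-1)/2` contrasts by the single-step
#' multivariate-normal (Tukey-type) procedure: each `p = 1 - P(max_j |T_j| <=
#' |z|)` under the joint normal law of the contrast statistics.
#'
#' @param fitted An `ehi_gamm` object.
#' @param term Name of a categorical model term.
#' @param conf_level Confidence level for the (unadjusted) Wald intervals.
#' @return A data frame with one row per level pair: `comparison` ("A/B",
#'   odds of A relative to B), `or`, `ci_low`, `ci_high`, `z`, `p_adjusted`.
#'   Zero rows if the term has a single level.
#' @export
pairwise_category_or <- function(fitted, term, conf_level = 0.95) {
  stopifnot(inherits(fitted, "ehi_gamm"))
  levs <- fitted$builders$xlevels[[term]]
  if (is.null(levs)) stop("'", term, "' is not a categorical model term", call. = FALSE)
  if (length(levs) < 2) {
    return(data.frame(comparison = character(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      z = numeric(0), p_adjusted = numeric(0)))
  }
  p_dense <- fitted$layout$p_dense
  xbar <- fitted$xbar_dense
  rows <- vapply(levs, function(l) .level_row(fitted, term, l, xbar),
                 numeric(p_dense))
  pairs <- utils::combn(length(levs), 2)
  m <- ncol(pairs)
  D <- matrix(0, fitted$layout$p, m)
  for (j in seq_len(m)) {
    D[seq_len(p_dense), j] <- rows[, pairs[1, j]] - rows[, pairs[2, j]]
  }
  log_or <- as.vector(crossprod(D, fitted$beta))
  VD <- as.matrix(Matrix::solve(fitted$Apen, D))
  C <- crossprod(D, VD)
  se <- sqrt(pmax(diag(C), 0))
  z <- ifelse(se > 0, log_or / se, 0)
  R <- suppressWarnings(stats::cov2cor(C))
  R[!is.finite(R)] <- 0; diag(R) <- 1
  p_adj <- vapply(seq_len(m), function(i) {
    if (m == 1) return(2 * pnorm(-abs(z[i])))
    pr <- with_local_seed(7L, mvtnorm::pmvnorm(
      lower = rep(-abs(z[i]), m), upper = rep(abs(z[i]), m),
      corr = R, abseps = 1e-4))
    max(min(1 - as.numeric(pr), 1), 0)
  }, numeric(1))
  zq <- -qnorm((1 - conf_level) / 2)
  data.frame(
    comparison = paste(levs[pairs[1, ]], levs[pairs[2, ]], sep = "/"),
    or = exp(log_or),
    ci_low = exp(log_or - zq * se),
    ci_high = exp(log_or + zq * se),
    z = z, p_adjusted = p_adj,
    stringsAsFactors = FALSE)
}

#' Absolute-probability surface over a covariate grid
#'
#' Predicts EHI probabilities on a grid of one or more model covariates, with
#' all non-varied terms held at their mean fitted contribution and random
#' effects at zero, then applies the class adjustment so probabilities are on
#' the absolute (population) scale. Suitable for plotting risk surfaces by,
#' say, race distance at several WBGT values with and without a previous
#' incident.
#'
#' @param fitted An `ehi_gamm` object.
#' @param sampling Sampling info for [adjust_probability()] (defaults to the
#'   one recorded at fit time).
#' @param grid Named list: covariate -> vector of values. Smooth covariates
#'   must lie within the training range; factor values must be known levels.
#' @return A long-format data frame: the expanded grid plus `prob_model` (on
#'   the down-sampled scale) and `prob_abs`.
#' @export
probability_surface <- function(fitted, sampling = fitted$sampling, grid) {
  stopifnot(inherits(fitted, "ehi_gamm"), length(grid) >= 1, !is.null(sampling))
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  p_dense <- fitted$layout$p_dense
  X <- matrix(fitted$xbar_dense, n, p_dense, byrow = TRUE)
  for (v in names(grid)) {
    blk <- fitted$layout$smooth_blocks[[v]]
    if (!is.null(blk)) {
      r <- fitted$builders$ranges[[v]]
      if (any(g[[v]] < r[1] | g[[v]] > r[2])) {
        stop("probability_surface: '", v, "' outside training range", call. = FALSE)
      }
      nd <- data.frame(x = g[[v]]); names(nd) <- v
      X[, blk$idx] <- mgcv::PredictMat(fitted$builders$smooths[[v]], nd)
    } else if (v %in% fitted$spec$factors) {
      levs <- fitted$builders$xlevels[[v]]
      vals <- as.character(g[[v]])
      if (any(!vals %in% levs)) {
        stop("probability_surface: unknown level in '", v, "'", call. = FALSE)
      }
      cols <- .focal_columns(fitted, v)
      X[, cols] <- outer(vals, levs[-1], `==`) * 1
    } else {
      stop("probability_surface: '", v, "' is not a model term", call. = FALSE)
    }
  }
  eta <- as.vector(X %*% fitted$beta[seq_len(p_dense)])
  g$prob_model <- plogis(eta)
  g$prob_abs <- adjust_probability(g$prob_model, sampling)
  g
}
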