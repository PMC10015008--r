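# Rare-event binomial GAMM: case-control down-sampling of non-events,
# penalized IRLS fitting with shrinkage cubic regression splines and
# horse/meet random intercepts, prediction, and the prior-correction class
# adjustment that restores absolute probabilities.
#
# The fitter maximises the penalized binomial log-likelihood by iteratively
# reweighted least squares on a sparse normal-equations representation
# (random intercepts enter as ridge-penalized indicator blocks, exactly the
# penalized-regression view of a GAMM), with smoothing parameters and
# random-effect precisions updated by the Fellner-Schall REML step
# lambda_j <- (p_j - lambda_j * tr(V S_j)) / (b_j' S_j b_j),
# where V is the inverse penalized information matrix. Spline bases and
# penalties are built by mgcv::smoothCon (basis "cs": cubic regression
# splines whose shrinkage penalty can send a whole term to the zero
# function), so fitted smooths live in the same basis mgcv users know, while
# the sparse solve keeps models with thousands of random-intercept levels
# tractable. Traces over the large random-effect blocks use a Hutchinson
# estimator with fixed Rademacher probes (the blocks are near-diagonal, so a
# handful of probes gives sub-percent accuracy); smooth-block traces are
# exact.

#' Run a block of code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so internal randomness (down-sampling,
#' fold assignment, trace probes) is reproducible without disturbing the
#' caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @export
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Model specification for the EHI binomial GAMM
#'
#' Describes the maximal (or any candidate) model: smooth terms fitted as
#' penalized cubic regression splines with shrinkage, categorical fixed
#' effects, and random intercepts. The default is the study's maximal model:
#' `ehi ~ s(age) + s(distance) + s(wbgt) + s(prev5) + going + prev_incident +
#' year + race_type + off_band + sex + re(horse) + re(meet)`.
#'
#' @param smooths Named integer vector: smooth covariate -> number of knots.
#' @param factors Character vector of categorical fixed-effect columns.
#' @param randoms Character vector of random-intercept grouping columns.
#' @param response Response column (binary 0/1), default `"ehi"`.
#' @return An object of class `ehi_model_spec`.
#' @seealso [fit_gamm()], [drop_term()]
#' @export
ehi_model_spec <- function(smooths = c(age = 10, distance_yards = 10,
                                       wbgt_c = 10, prev5_c = 10),
                           factors = c("going5", "prev_incident", "year",
                                       "race_type", "off_band", "sex"),
                           randoms = c("horse_id", "meet_id"),
                           response = "ehi") {
  terms <- c(names(smooths), factors, randoms)
  if (anyDuplicated(terms)) {
    stop("ehi_model_spec: duplicated term: ",
         terms[duplicated(terms)][1], call. = FALSE)
  }
  spec <- list(smooths = smooths, factors = factors, randoms = randoms,
               response = response)
  class(spec) <- "ehi_model_spec"
  spec
}

#' @rdname ehi_model_spec
#' @param spec An `ehi_model_spec`.
#' @param term Term name to remove (a smooth covariate or factor; random
#'   intercepts are never selection candidates and cannot be dropped).
#' @export
drop_term <- function(spec, term) {
  if (term %in% names(spec$smooths)) {
    spec$smooths <- spec$smooths[setdiff(names(spec$smooths), term)]
  } else if (term %in% spec$factors) {
    spec$factors <- setdiff(spec$factors, term)
  } else {
    stop("drop_term: '", term, "' is not a removable term", call. = FALSE)
  }
  spec
}

#' @rdname ehi_model_spec
#' @export
removable_terms <- function(spec) {
  c(names(spec$smooths), spec$factors)
}

#' @rdname ehi_model_spec
#' @export
spec_label <- function(spec) {
  rhs <- c(sprintf("s(%s)", names(spec$smooths)), spec$factors,
           sprintf("re(%s)", spec$randoms))
  paste(spec$response, "~", paste(rhs, collapse = " + "))
}

#' Fitting control parameters
#'
#' @param efs_maxit Maximum Fellner-Schall smoothing updates (default 30).
#' @param efs_tol Convergence tolerance on max |change in log(lambda)|.
#' @param irls_maxit Maximum IRLS iterations per smoothing update.
#' @param irls_tol Relative penalized-deviance convergence tolerance.
#' @param probe_count Rademacher probes for random-effect block traces.
#' @param probe_seed Seed for the (fixed) probe matrix.
#' @param lambda_min,lambda_max Bounds on smoothing parameters.
#' @param coef_cap Absolute coefficient value beyond which a quasi-separation
#'   warning is issued.
#' @return A list of class `ehi_gamm_control`.
#' @export
gamm_control <- function(efs_maxit = 30L, efs_tol = 0.02, irls_maxit = 100L,
                         irls_tol = 1e-9, probe_count = 20L, probe_seed = 101L,
                         lambda_min = 1e-6, lambda_max = 1e8, coef_cap = 18) {
  structure(list(efs_maxit = efs_maxit, efs_tol = efs_tol,
                 irls_maxit = irls_maxit, irls_tol = irls_tol,
                 probe_count = probe_count, probe_seed = probe_seed,
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 coef_cap = coef_cap),
            class = "ehi_gamm_control")
}

#' Down-sample non-events to a fixed control:case ratio
#'
#' Retains all cases and a simple random sample of `round(ratio * n_cases)`
#' controls (the case-control device that makes the rare-event fit
#' tractable; with ratio 10 the 0.1% incidence rises to about 9%). The true
#' and sampled case fractions are recorded so absolute probabilities can be
#' recovered later by [adjust_probability()].
#'
#' @param frame A model frame with the response column.
#' @param ratio Controls per case (default 10).
#' @param seed Optional seed for the control sample.
#' @param response Response column name.
#' @return The down-sampled frame, with a `"sampling"` attribute: a list with
#'   `q` (case fraction in the returned frame), `pi` (case fraction in
#'   `frame`), `ratio` and `seed`.
#' @export
downsample_controls <- function(frame, ratio = 10, seed = NULL,
                                response = "ehi") {
  y <- frame[[response]]
  cases <- which(y == 1L)
  controls <- which(y == 0L)
  if (!length(cases)) stop("downsample_controls: no cases in frame", call. = FALSE)
  n_ctrl <- round(ratio * length(cases))
  if (n_ctrl > length(controls)) {
    warning("downsample_controls: fewer controls than requested; keeping all")
    keep_ctrl <- controls
  } else {
    keep_ctrl <- with_local_seed(seed, sample(controls, n_ctrl))
  }
  keep <- sort(c(cases, keep_ctrl))
  out <- frame[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sampling") <- list(q = length(cases) / length(keep),
                                pi = length(cases) / length(y),
                                ratio = ratio, seed = seed)
  out
}

#' Class adjustment of down-sampled probabilities
#'
#' Prior-correction on the odds scale for probabilities estimated from
#' case-control down-sampled data: with `q` the case fraction in the fitted
#' data and `pi` the true case fraction,
#' `odds_adj = odds(p) * pi (1 - q) / (q (1 - pi))`. Strictly increasing in
#' `p`; maps 0 to 0 and 1 to 1; the identity when `q == pi`.
#'
#' @param p Probabilities on the fitted (down-sampled) scale.
#' @param sampling A sampling-info list with elements `q` and `pi` (as
#'   attached by [downsample_controls()]).
#' @return Absolute (population-scale) probabilities.
#' @export
adjust_probability <- function(p, sampling) {
  stopifnot(all(p >= 0 & p <= 1), sampling$q > 0, sampling$q < 1,
            sampling$pi > 0, sampling$pi < 1)
  r <- (sampling$pi * (1 - sampling$q)) / (sampling$q * (1 - sampling$pi))
  out <- p * r / (1 - p + p * r)
  out[p == 1] <- 1
  out
}

## ---------------------------------------------------------------------
## design construction

.build_builders <- function(frame, spec, control) {
  n <- nrow(frame)
  smooths <- list()
  ranges <- list()
  Xs <- NULL
  for (v in names(spec$smooths)) {
    x <- frame[[v]]
    if (is.null(x)) stop("fit_gamm: missing smooth covariate '", v, "'", call. = FALSE)
    u <- length(unique(x))
    k <- max(4L, min(spec$smooths[[v]], u - 1L))
    sm <- mgcv::smoothCon(do.call(mgcv::s, list(as.name(v), bs = "cs", k = k)),
                          data = frame, absorb.cons = TRUE)[[1]]
    smooths[[v]] <- sm
    ranges[[v]] <- range(x)
    Xs <- cbind(Xs, sm$X)
  }
  xlevels <- list()
  if (length(spec$factors)) {
    for (v in spec$factors) {
      f <- frame[[v]]
      if (is.null(f)) stop("fit_gamm: missing factor '", v, "'", call. = FALSE)
      xlevels[[v]] <- levels(droplevels(as.factor(f)))
      if (length(xlevels[[v]]) < 2) {
        stop("fit_gamm: factor '", v, "' has a single observed level", call. = FALSE)
      }
    }
    ff <- as.formula(paste("~", paste(spec$factors, collapse = " + ")))
    dat <- frame[spec$factors]
    for (v in spec$factors) dat[[v]] <- factor(dat[[v]], levels = xlevels[[v]])
    Xp <- model.matrix(ff, dat)
  } else {
    Xp <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  par_assign <- attr(Xp, "assign")
  randoms <- list()
  for (v in spec$randoms) {
    f <- droplevels(as.factor(frame[[v]]))
    randoms[[v]] <- levels(f)
  }
  list(spec = spec, smooths = smooths, ranges = ranges, xlevels = xlevels,
       par_assign = par_assign, par_names = colnames(Xp),
       p_par = ncol(Xp), randoms = randoms,
       Xd_train = cbind(Xp, Xs))
}

# Dense part of the linear-predictor matrix for new data; smooth covariates
# clamped to the training range (warns), unseen factor levels are an error.
.design_dense <- function(builders, data, clamp = TRUE) {
  n <- nrow(data)
  spec <- builders$spec
  if (length(spec$factors)) {
    dat <- data[spec$factors]
    for (v in spec$factors) {
      vals <- as.character(data[[v]])
      bad <- !vals %in% builders$xlevels[[v]]
      if (any(bad)) {
        stop("predict: unseen level '", vals[which(bad)[1]], "' in factor '",
             v, "'", call. = FALSE)
      }
      dat[[v]] <- factor(vals, levels = builders$xlevels[[v]])
    }
    ff <- as.formula(paste("~", paste(spec$factors, collapse = " + ")))
    Xp <- model.matrix(ff, dat)
  } else {
    Xp <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  Xs <- NULL
  for (v in names(builders$smooths)) {
    x <- data[[v]]
    r <- builders$ranges[[v]]
    if (clamp && any(x < r[1] | x > r[2], na.rm = TRUE)) {
      warning("predict: '", v, "' outside training range; clamped to [",
              signif(r[1], 4), ", ", signif(r[2], 4), "]")
      x <- pmin(pmax(x, r[1]), r[2])
    }
    nd <- data.frame(x = x); names(nd) <- v
    Xs <- cbind(Xs, mgcv::PredictMat(builders$smooths[[v]], nd))
  }
  cbind(Xp, Xs)
}

## ---------------------------------------------------------------------
## sparse normal equations: A = X'WX assembled blockwise so that models with
## thousands of random-intercept levels never form a dense cross-product.

.assemble_A <- function(Xd, gs, Ls, w) {
  .sp <- function(m) {
    methods::as(methods::as(Matrix::Matrix(m), "generalMatrix"), "CsparseMatrix")
  }
  nre <- length(gs)
  blocks <- vector("list", nre + 1)
  blocks[[1]] <- vector("list", nre + 1)
  blocks[[1]][[1]] <- .sp(crossprod(Xd * sqrt(w)))
  if (nre) {
    for (i in seq_len(nre)) {
      C <- rowsum(Xd * w, gs[[i]], reorder = TRUE)  # Ls[i] x pd (all levels occur)
      blocks[[1]][[i + 1]] <- .sp(t(C))
    }
    for (i in seq_len(nre)) {
      row <- vector("list", nre + 1)
      row[[1]] <- Matrix::t(blocks[[1]][[i + 1]])
      for (j in seq_len(nre)) {
        if (j < i) {
          row[[j + 1]] <- Matrix::t(blocks[[j + 1]][[i + 1]])
        } else if (j == i) {
          row[[j + 1]] <- Matrix::Diagonal(
            Ls[i], as.vector(rowsum(w, gs[[i]], reorder = TRUE)))
        } else {
          row[[j + 1]] <- Matrix::sparseMatrix(i = gs[[i]], j = gs[[j]], x = w,
                                               dims = c(Ls[i], Ls[j]))
        }
      }
      blocks[[i + 1]] <- row
    }
  }
  rows <- lapply(blocks, function(r) do.call(cbind, r))
  Matrix::forceSymmetric(do.call(rbind, rows))
}

.penalty_matrix <- function(layout, lambda) {
  Sd <- matrix(0, layout$p_dense, layout$p_dense)
  for (b in layout$smooth_blocks) {
    Sd[b$idx, b$idx] <- lambda[[b$name]] * b$S
  }
  parts <- list(methods::as(methods::as(Matrix::Matrix(Sd), "generalMatrix"),
                            "CsparseMatrix"))
  for (b in layout$re_blocks) {
    parts[[length(parts) + 1]] <- Matrix::Diagonal(b$L, lambda[[b$name]])
  }
  ridge <- Matrix::Diagonal(layout$p, 1e-9)
  Matrix::forceSymmetric(Matrix::bdiag(parts)) + ridge
}

#' Fit the rare-event binomial GAMM
#'
#' Maximises the penalized binomial log-likelihood (logit link) by IRLS on a
#' sparse normal-equations representation. Smooth terms use cubic regression
#' splines with shrinkage (basis "cs", built by mgcv), so a smooth can be
#' penalized all the way to the zero function; random intercepts are
#' zero-mean ridge-penalized indicator blocks, predicting 0 for groups unseen
#' at fit time. Smoothing parameters and random-effect precisions are chosen
#' by Fellner-Schall REML updates (a marginal-likelihood criterion).
#'
#' @param frame Model frame (e.g. from [build_model_frame()], possibly
#'   down-sampled by [downsample_controls()]).
#' @param spec An [ehi_model_spec()].
#' @param lambda_init Optional named vector of starting smoothing parameters
#'   (warm start, e.g. across cross-validation folds).
#' @param lambda_fixed Optional named vector: skip smoothing-parameter
#'   estimation and fit at exactly these values (useful to verify that
#'   lambda -> Inf shrinks a term to zero).
#' @param control A [gamm_control()] list.
#' @return An object of class `ehi_gamm`: coefficients, per-term smoothing
#'   parameters `lambda`, per-term effective degrees of freedom `edf`, the
#'   penalized information matrix (whose inverse is the coefficient
#'   covariance), deviance and convergence information. The `"sampling"`
#'   attribute of `frame`, if any, is carried in `$sampling`.
#' @export
fit_gamm <- function(frame, spec, lambda_init = NULL, lambda_fixed = NULL,
                     control = gamm_control()) {
  y <- frame[[spec$response]]
  if (is.null(y) || !all(y %in% c(0L, 1L))) {
    stop("fit_gamm: response must be binary 0/1", call. = FALSE)
  }
  n <- length(y)
  builders <- .build_builders(frame, spec, control)
  Xd <- builders$Xd_train
  p_par <- builders$p_par
  p_dense <- ncol(Xd)

  ## block layout -------------------------------------------------------
  smooth_blocks <- list()
  pos <- p_par
  for (v in names(builders$smooths)) {
    k <- ncol(builders$smooths[[v]]$X)
    smooth_blocks[[v]] <- list(name = v, idx = pos + seq_len(k),
                               S = builders$smooths[[v]]$S[[1]], p = k)
    pos <- pos + k
  }
  gs <- list(); Ls <- integer(0); re_blocks <- list()
  pos <- p_dense
  for (v in spec$randoms) {
    lev <- builders$randoms[[v]]
    g <- match(as.character(frame[[v]]), lev)
    gs[[v]] <- g
    Ls[v] <- length(lev)
    re_blocks[[v]] <- list(name = v, idx = pos + seq_along(lev),
                           L = length(lev), p = length(lev))
    pos <- pos + length(lev)
  }
  p <- pos
  layout <- list(p = p, p_dense = p_dense, p_par = p_par,
                 smooth_blocks = smooth_blocks, re_blocks = re_blocks)
  pen_names <- c(names(smooth_blocks), names(re_blocks))

  lambda <- setNames(rep(1, length(pen_names)), pen_names)
  if (!is.null(lambda_init)) {
    lambda[intersect(names(lambda_init), pen_names)] <-
      pmin(pmax(lambda_init[intersect(names(lambda_init), pen_names)],
                control$lambda_min), control$lambda_max)
  }
  fixed <- FALSE
  if (!is.null(lambda_fixed)) {
    lambda[names(lambda_fixed)] <- lambda_fixed
    fixed <- TRUE
  }

  ## fixed Rademacher probes for the big random-effect traces ------------
  probes <- with_local_seed(control$probe_seed, lapply(re_blocks, function(b) {
    m <- control$probe_count
    Matrix::sparseMatrix(i = rep(b$idx, m), j = rep(seq_len(m), each = b$p),
                         x = sample(c(-1, 1), b$p * m, replace = TRUE),
                         dims = c(p, m))
  }))

  eta <- rep(qlogis((sum(y) + 0.5) / (n + 1)), n)
  beta <- numeric(p)
  beta[1] <- eta[1]
  irls_converged <- FALSE

  pen_dev <- function(bb, eta_b, S) {
    mu_b <- plogis(eta_b)
    -2 * sum(y * log(pmax(mu_b, 1e-12)) +
               (1 - y) * log(pmax(1 - mu_b, 1e-12))) +
      sum(bb * as.vector(S %*% bb))
  }
  eta_of <- function(bb) {
    e <- as.vector(Xd %*% bb[seq_len(p_dense)])
    for (v in names(gs)) e <- e + bb[re_blocks[[v]]$idx][gs[[v]]]
    pmin(pmax(e, -30), 30)
  }

  # Penalized IRLS with strictly monotone step-halving: a step that cannot
  # be made non-increasing is rejected outright, so the iterate never
  # diverges even for near-separated configurations.
  run_irls <- function(beta, eta, lambda) {
    S <- .penalty_matrix(layout, as.list(lambda))
    dev_cur <- pen_dev(beta, eta, S)
    for (it in seq_len(control$irls_maxit)) {
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      wz <- w * z
      b <- c(crossprod(Xd, wz))
      for (v in names(gs)) b <- c(b, as.vector(rowsum(wz, gs[[v]], reorder = TRUE)))
      A <- .assemble_A(Xd, gs, Ls, w)
      Ch <- Matrix::Cholesky(A + S, LDL = FALSE, super = TRUE)
      beta_new <- as.vector(Matrix::solve(Ch, b))
      step <- 1
      accepted <- FALSE
      while (step >= 1 / 1024) {
        bb <- beta + step * (beta_new - beta)
        if (all(is.finite(bb))) {
          eta_new <- eta_of(bb)
          dev_new <- pen_dev(bb, eta_new, S)
          if (is.finite(dev_new) && dev_new <= dev_cur + 1e-8) {
            accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
      if (!accepted) {  # no descent step exists: current beta is the optimum
        irls_converged <<- TRUE
        break
      }
      delta <- abs(dev_cur - dev_new)
      beta <- bb; eta <- eta_new; dev_cur <- dev_new
      if (delta < control$irls_tol * (abs(dev_new) + 1)) {
        irls_converged <<- TRUE
        break
      }
    }
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- .assemble_A(Xd, gs, Ls, w)
    Ch <- Matrix::Cholesky(A + S, LDL = FALSE, super = TRUE)
    list(beta = beta, eta = eta, Ch = Ch, Apen = A + S, S = S)
  }

  traces <- function(st, lambda) {
    out <- setNames(numeric(length(pen_names)), pen_names)
    for (b in layout$smooth_blocks) {
      E <- Matrix::sparseMatrix(i = b$idx, j = seq_len(b$p), x = 1,
                                dims = c(p, b$p))
      U <- as.matrix(Matrix::solve(st$Ch, E))[b$idx, , drop = FALSE]
      out[b$name] <- sum(U * b$S)
    }
    for (b in layout$re_blocks) {
      Z <- probes[[b$name]]
      V <- Matrix::solve(st$Ch, Z)
      out[b$name] <- sum(Z * V) / ncol(Z)
    }
    out
  }

  efs_converged <- !length(pen_names) || fixed
  st <- run_irls(beta, eta, lambda)
  outer_used <- 0L
  if (length(pen_names) && !fixed) {
    for (outer in seq_len(control$efs_maxit)) {
      outer_used <- outer
      tr <- traces(st, lambda)
      lam_new <- lambda
      for (nm in pen_names) {
        blk <- c(layout$smooth_blocks, layout$re_blocks)[[nm]]
        bj <- st$beta[blk$idx]
        bSb <- if (is.null(blk$S)) sum(bj^2) else
          as.numeric(crossprod(bj, blk$S %*% bj))
        num <- max(blk$p - lambda[nm] * tr[nm], 1e-8)
        lam <- if (bSb > 1e-12) num / bSb else control$lambda_max
        lam <- min(max(lam, lambda[nm] / 10), lambda[nm] * 10)
        lam_new[nm] <- min(max(lam, control$lambda_min), control$lambda_max)
      }
      delta <- max(abs(log(lam_new / lambda)))
      lambda <- lam_new
      st <- run_irls(st$beta, st$eta, lambda)
      if (delta < control$efs_tol) {
        efs_converged <- TRUE
        break
      }
    }
  }

  ## effective degrees of freedom per penalized term ---------------------
  tr <- if (length(pen_names)) traces(st, lambda) else numeric(0)
  edf <- setNames(numeric(length(pen_names)), pen_names)
  for (nm in pen_names) {
    blk <- c(layout$smooth_blocks, layout$re_blocks)[[nm]]
    edf[nm] <- max(blk$p - lambda[nm] * tr[nm], 0)
  }

  if (max(abs(st$beta[seq_len(p_dense)])) > control$coef_cap) {
    warning("fit_gamm: large coefficient magnitude; possible quasi-separation")
  }

  coef_names <- c(builders$par_names,
                  unlist(lapply(names(smooth_blocks), function(v)
                    paste0("s(", v, ").", seq_len(smooth_blocks[[v]]$p)))),
                  unlist(lapply(names(re_blocks), function(v)
                    paste0("re(", v, ").", builders$randoms[[v]]))))
  fit <- list(beta = setNames(st$beta, coef_names),
              lambda = lambda, edf = edf,
              edf_total = builders$p_par + sum(edf),
              layout = layout, builders = builders,
              spec = spec, control = control,
              Apen = st$Apen,
              fitted = plogis(st$eta),
              deviance = -2 * sum(y * log(pmax(plogis(st$eta), 1e-12)) +
                                    (1 - y) * log(pmax(1 - plogis(st$eta), 1e-12))),
              n = n, y_mean = mean(y),
              xbar_dense = colMeans(Xd),
              converged = list(irls = irls_converged, efs = efs_converged,
                               efs_iter = outer_used),
              sampling = attr(frame, "sampling"))
  fit$builders$Xd_train <- NULL  # not needed after fitting; keep objects lean
  class(fit) <- "ehi_gamm"
  fit
}

#' @method print ehi_gamm
#' @export
print.ehi_gamm <- function(x, ...) {
  cat("Binomial GAMM (penalized IRLS, Fellner-Schall REML)\n")
  cat("  n =", x$n, " case fraction =", signif(x$y_mean, 3), "\n")
  cat("  terms:", spec_label(x$spec), "\n")
  if (length(x$edf)) {
    cat("  edf: ", paste(sprintf("%s=%.2f", names(x$edf), x$edf),
                         collapse = ", "), "\n")
  }
  cat("  deviance =", signif(x$deviance, 6), "\n")
  invisible(x)
}

#' Predicted EHI probabilities on the fitted (down-sampled) scale
#'
#' Inverse-logit of the linear predictor for new data. Smooth covariates
#' outside the training range are clamped to the range endpoints (with a
#' warning); random intercepts for horses or meets not seen at fit time are
#' 0, and all random intercepts are 0 when `include_random = FALSE`. Unseen
#' categorical levels are an error.
#'
#' @param fitted An `ehi_gamm` object.
#' @param newdata Data frame with the model covariates.
#' @param include_random Add estimated random intercepts for known groups?
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @return Numeric vector of predictions.
#' @export
predict_probability <- function(fitted, newdata, include_random = TRUE,
                                type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(inherits(fitted, "ehi_gamm"))
  Xd <- .design_dense(fitted$builders, newdata, clamp = TRUE)
  eta <- as.vector(Xd %*% fitted$beta[seq_len(fitted$layout$p_dense)])
  if (include_random) {
    for (b in fitted$layout$re_blocks) {
      idx <- match(as.character(newdata[[b$name]]),
                   fitted$builders$randoms[[b$name]])
      bcoef <- fitted$beta[b$idx]
      eta <- eta + ifelse(is.na(idx), 0, bcoef[idx])
    }
  }
  if (type == "link") eta else plogis(eta)
}

# Variance of a linear contrast d'beta from the inverse penalized
# information matrix (Bayesian covariance of the penalized fit).
.contrast_var <- function(fit, d) {
  v <- Matrix::solve(fit$Apen, d)
  max(sum(d * as.vector(v)), 0)
}

#' Parametric coefficient table with standard errors
#'
#' Estimates and standard errors for the unpenalized (categorical/intercept)
#' coefficients, from the inverse penalized information matrix. Useful for
#' case-control invariance checks: non-intercept coefficients from a
#' full-data fit and a down-sampled fit should agree within sampling error,
#' while the intercept absorbs the sampling-rate shift.
#'
#' @param fitted An `ehi_gamm` object.
#' @return Data frame with `term`, `estimate`, `se`.
#' @export
parametric_coefficients <- function(fitted) {
  stopifnot(inherits(fitted, "ehi_gamm"))
  idx <- seq_len(fitted$layout$p_par)
  se <- vapply(idx, function(i) {
    d <- numeric(fitted$layout$p); d[i] <- 1
    sqrt(.contrast_var(fitted, d))
  }, numeric(1))
  data.frame(term = names(fitted$beta)[idx],
             estimate = unname(fitted$beta[idx]), se = se,
             stringsAsFactors = FALSE)
}
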