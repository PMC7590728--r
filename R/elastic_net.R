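# Standardization helper: population convention (divisor n), so that the
# coordinate-descent update denominator is exactly 1 + lambda*(1-alpha).
.standardize <- function(x) {
  n <- nrow(x)
  xm <- colMeans(x)
  xc <- sweep(x, 2L, xm, "-")
  xs <- sqrt(colMeans(xc^2))
  ok <- xs > 0
  xstd <- xc
  if (any(ok)) xstd[, ok] <- sweep(xc[, ok, drop = FALSE], 2L, xs[ok], "/")
  list(x = xstd, mean = xm, sd = xs, ok = ok)
}

.enet_objective <- function(xstd, yc, beta, alpha, lambda) {
  n <- nrow(xstd)
  r <- yc - xstd %*% beta
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Fit an elastic-net linear model by cyclic coordinate descent
#'
#' Minimizes `(1/2n) * sum((y - b0 - x b)^2) + lambda * (alpha*||b||_1 +
#' (1-alpha)/2 * ||b||_2^2)`. Predictors are standardized internally to
#' unit population variance and the response is centered; coordinate
#' updates use soft-thresholding with warm starts along a descending
#' penalty path. Per path step, candidates are screened by the
#' sequential strong rule and the Karush-Kuhn-Tucker conditions are then
#' verified over all predictors, admitting any violator and repeating —
#' screening accelerates the solve without changing the solution.
#' Coefficients are returned on the original predictor scale with the
#' intercept adjusted accordingly.
#'
#' @param x numeric matrix, samples x predictors; no missing values.
#' @param y numeric response vector.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param lambda a single penalty or a descending path of penalties.
#' @param tol convergence tolerance: a penalty step converges when the
#'   largest squared coefficient update in a sweep (standardized scale)
#'   falls below `tol * var(y)`, making the criterion invariant to the
#'   response scale.
#' @param maxit maximum number of sweeps per penalty.
#' @param warmStart optional initial coefficients on the original scale
#'   (named or positional, length `ncol(x)`).
#' @return For a single `lambda`: list with `intercept`, `beta` (named,
#'   original scale), `betaStd` (standardized scale), `niter`,
#'   `converged`. For a path: the same with `beta`/`betaStd` as
#'   predictors x lambdas matrices and vector `intercept`.
#' @seealso [kktCheck()] for an independent optimality check.
#' @export
elasticNetFit <- function(x, y, alpha, lambda, tol = 1e-7, maxit = 1e5,
                          warmStart = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite with no missing values")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 2) stop("need at least 2 observations")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (length(lambda) > 1 && is.unsorted(rev(lambda)))
    stop("a lambda path must be descending")
  std <- .standardize(x)
  yc <- y - mean(y)
  p <- ncol(x)
  ok <- std$ok
  init <- NULL
  if (!is.null(warmStart)) {
    if (length(warmStart) != p) stop("warmStart has wrong length")
    init <- (warmStart * std$sd)[ok]
  }
  fit <- .cd_enet_path(std$x[, ok, drop = FALSE], yc, as.numeric(lambda),
                       alpha, tol, as.integer(maxit), init)
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop(errorCondition(
      sprintf("coordinate descent did not converge at lambda = %g within %d sweeps",
              lambda[bad], as.integer(maxit)),
      class = c("enetNonconvergence", "error", "condition"),
      iterate = fit$beta))
  }
  nlam <- length(lambda)
  betaStd <- matrix(0, p, nlam)
  betaStd[ok, ] <- fit$beta
  beta <- betaStd
  beta[ok, ] <- betaStd[ok, , drop = FALSE] / std$sd[ok]
  intercept <- mean(y) - as.numeric(crossprod(beta, std$mean))
  rownames(betaStd) <- rownames(beta) <- colnames(x)
  if (nlam == 1L)
    list(intercept = intercept[1], beta = beta[, 1], betaStd = betaStd[, 1],
         niter = fit$niter[1], converged = TRUE)
  else
    list(intercept = intercept, beta = beta, betaStd = betaStd,
         niter = fit$niter, converged = fit$converged)
}

#' Check elastic-net KKT optimality conditions
#'
#' An optimality oracle independent of the solver path: at the exact
#' solution of the standardized elastic-net problem, every nonzero
#' coefficient satisfies `(1/n) x_j' r - lambda*(1-alpha)*b_j =
#' lambda*alpha*sign(b_j)` and every zero coefficient satisfies
#' `|(1/n) x_j' r| <= lambda*alpha` (with `r` the residual on the
#' standardized scale). Returns the largest violation.
#'
#' @param x,y the data as passed to [elasticNetFit()].
#' @param alpha,lambda the penalty configuration (single `lambda`).
#' @param beta coefficients on the original predictor scale.
#' @return list with `max_violation` and the per-coefficient
#'   `violations` vector.
#' @export
kktCheck <- function(x, y, alpha, lambda, beta) {
  x <- as.matrix(x)
  std <- .standardize(x)
  yc <- y - mean(y)
  n <- nrow(x)
  bstd <- beta * std$sd
  r <- yc - std$x %*% bstd
  g <- as.numeric(crossprod(std$x, r)) / n
  viol <- numeric(length(bstd))
  nz <- bstd != 0 & std$ok
  viol[nz] <- abs(g[nz] - lambda * (1 - alpha) * bstd[nz] -
                    lambda * alpha * sign(bstd[nz]))
  z <- !nz & std$ok
  viol[z] <- pmax(0, abs(g[z]) - lambda * alpha)
  list(max_violation = if (length(viol)) max(viol) else 0,
       violations = setNames(viol, colnames(x)))
}

#' Build a log-spaced descending penalty grid
#'
#' The grid runs from `lambda_max = max_j |x_j'(y - mean(y))| / (n *
#' alpha)` — the smallest penalty at which the fitted model is all-zero
#' — down to `lambda_max * minRatio`, log-spaced.
#'
#' @param x,y the training data (`x` is standardized internally, as in
#'   [elasticNetFit()]).
#' @param alpha elastic-net mixing, must be > 0 (at `alpha = 0` no
#'   finite penalty zeroes the model; supply an explicit grid instead).
#' @param nLambda grid length, default 100.
#' @param minRatio ratio of smallest to largest penalty, default 1e-4.
#' @return descending numeric vector of penalties.
#' @export
makeLambdaGrid <- function(x, y, alpha, nLambda = 100, minRatio = 1e-4) {
  if (alpha <= 0)
    stop("alpha = 0 gives an unbounded lambda_max; supply an explicit grid")
  std <- .standardize(as.matrix(x))
  yc <- y - mean(y)
  lam_max <- max(abs(crossprod(std$x, yc))) / (nrow(std$x) * alpha)
  if (!is.finite(lam_max) || lam_max <= 0)
    stop("degenerate data: cannot determine lambda_max")
  # tiny inflation so the top of the grid is all-zero despite rounding
  lam_max <- lam_max * (1 + 1e-9)
  if (nLambda == 1L) return(lam_max)
  exp(seq(log(lam_max), log(lam_max * minRatio), length.out = nLambda))
}

#' Cross-validate an elastic-net penalty path
#'
#' Randomly partitions the samples into `k` near-equal folds
#' (deterministic given `seed`), fits the full penalty path on each
#' k-1-fold training split with warm starts, and averages held-out
#' squared error per penalty. The selected penalty minimizes the mean
#' CV MSE; ties break toward the larger (more penalized, sparser)
#' penalty.
#'
#' @param x,y the training data.
#' @param alpha elastic-net mixing.
#' @param lambda descending penalty grid (see [makeLambdaGrid()]).
#' @param k fold count, default 10.
#' @param seed integer seed for the fold assignment.
#' @param tol,maxit solver controls, as in [elasticNetFit()].
#' @return A [CVResult-class].
#' @export
crossValidate <- function(x, y, alpha, lambda, k = 10, seed = 1L,
                          tol = 1e-7, maxit = 1e5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than samples")
  folds <- .with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  nlam <- length(lambda)
  fold_mse <- matrix(NA_real_, k, nlam)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- elasticNetFit(x[tr, , drop = FALSE], y[tr], alpha, lambda,
                         tol = tol, maxit = maxit)
    pred <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2L, fit$intercept, "+")
    fold_mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cvm <- colMeans(fold_mse)
  cvsd <- apply(fold_mse, 2L, sd) / sqrt(k)
  sel <- which.min(cvm)  # first minimum in a descending grid = largest lambda
  new("CVResult", lambda = as.numeric(lambda), cvm = cvm, cvsd = cvsd,
      lambdaSel = lambda[sel], k = as.integer(k),
      foldSeed = as.integer(seed))
}

#' Train an epigenetic clock on a methylation cohort
#'
#' The full training protocol: chronological age is regressed on the
#' beta values of all probes by elastic-net penalized regression
#' (default mixing `alpha = 0.5`), with the penalty minimizing the
#' 10-fold cross-validated mean squared error, then refit on the full
#' training set at the selected penalty. Missing beta values are
#' imputed with training-set probe means (recorded in the model
#' provenance so the same means can be reused at prediction time);
#' all-missing probes are dropped with a warning. The returned clock
#' holds only the nonzero coefficients, on the raw beta scale.
#'
#' @param train a [BetaSet-class] with at least 20 samples.
#' @param alpha elastic-net mixing, default 0.5.
#' @param k CV fold count, default 10.
#' @param nLambda,minRatio penalty-grid controls (see
#'   [makeLambdaGrid()]).
#' @param missingPolicy `"mean"` (probe-mean imputation, default) or
#'   `"error"`.
#' @param ageUnit `"years"` (default) or `"days"`. The elastic-net
#'   problem is solved on the years scale either way; `"days"` rescales
#'   the stored intercept, coefficients, and penalty by 365.25, the
#'   exact day-scale equivalent of the fit (reference solvers
#'   standardize the response internally, which makes the day- and
#'   year-scale regressions the same problem). Predictions are always
#'   returned in years.
#' @param probeSetTag free-text label of the probe universe (e.g.
#'   `"epic_all"`, `"common_450k"`), stored in provenance.
#' @param seed integer seed for the CV fold assignment.
#' @param tol,maxit solver controls.
#' @return list with `model` ([ClockModel-class]) and `cv`
#'   ([CVResult-class]).
#' @export
trainClock <- function(train, alpha = 0.5, k = 10, nLambda = 100,
                       minRatio = 1e-4, missingPolicy = c("mean", "error"),
                       ageUnit = c("years", "days"), probeSetTag = "all",
                       seed = 1L, tol = 1e-7, maxit = 1e5) {
  missingPolicy <- match.arg(missingPolicy)
  ageUnit <- match.arg(ageUnit)
  if (ncol(train) < 20) stop("need at least 20 training samples")
  y <- unname(sampleAges(train))
  if (sd(y) == 0) stop("degenerate response: constant age in training set")
  unit_scale <- if (ageUnit == "days") .DAYS_PER_YEAR else 1

  x <- t(betaValues(train))
  if (anyNA(x)) {
    if (missingPolicy == "error") stop("missing beta values in training set")
    all_missing <- colSums(!is.na(x)) == 0
    if (any(all_missing)) {
      warning(sum(all_missing), " all-missing probe(s) dropped")
      x <- x[, !all_missing, drop = FALSE]
    }
    pm <- colMeans(x, na.rm = TRUE)
    na_ix <- which(is.na(x), arr.ind = TRUE)
    if (nrow(na_ix)) x[na_ix] <- pm[na_ix[, 2L]]
  }
  probe_means <- colMeans(x)

  grid <- makeLambdaGrid(x, y, alpha, nLambda = nLambda, minRatio = minRatio)
  cv <- crossValidate(x, y, alpha, grid, k = k, seed = seed,
                      tol = tol, maxit = maxit)
  sel <- match(cv@lambdaSel, grid)
  full <- elasticNetFit(x, y, alpha, grid[seq_len(sel)],
                        tol = tol, maxit = maxit)
  beta <- if (sel == 1L && is.null(dim(full$beta))) full$beta
          else full$beta[, sel]
  b0 <- if (length(full$intercept) > 1L) full$intercept[sel] else full$intercept
  nz <- beta != 0
  model <- ClockModel(
    intercept = b0 * unit_scale, coefficients = beta[nz] * unit_scale,
    provenance = list(alpha = alpha, lambda = cv@lambdaSel * unit_scale,
                      n_train = ncol(train), probe_set = probeSetTag,
                      seed = as.integer(seed), age_unit = ageUnit,
                      n_lambda = nLambda, min_ratio = minRatio, k = k,
                      missing_policy = missingPolicy,
                      probe_means = probe_means[nz]))
  list(model = model, cv = cv)
}
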