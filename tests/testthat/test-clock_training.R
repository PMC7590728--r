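test_that("unpenalized fit matches the normal-equations OLS solution", {
  set.seed(101)
  n <- 60; p <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- 1 + x %*% c(2, -1, 0.5) + rnorm(n)
  fit <- elasticNetFit(x, y, alpha = 0.5, lambda = 0, tol = 1e-18)
  # oracle: closed-form OLS from the normal equations
  xa <- cbind(1, x)
  ols <- solve(crossprod(xa), crossprod(xa, y))
  expect_lt(max(abs(c(fit$intercept, fit$beta) - ols)), 1e-6)
})

test_that("univariate lasso equals the soft-threshold closed form", {
  set.seed(102)
  n <- 80
  x <- matrix(rnorm(n), n, 1)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # standardized, sd_n = 1
  y <- 0.7 * x[, 1] + rnorm(n, sd = 0.3)
  yc <- y - mean(y)
  for (lam in c(0.01, 0.2, 0.5, 2)) {
    fit <- elasticNetFit(x, y, alpha = 1, lambda = lam, tol = 1e-18)
    z <- sum(x[, 1] * yc) / n
    oracle <- sign(z) * max(abs(z) - lam, 0)
    expect_lt(abs(fit$beta[1] - oracle), 1e-8)
  }
})

test_that("solutions satisfy the KKT conditions on random instances", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(20:100, 1); p <- sample(2:20, 1)
    x <- matrix(rnorm(n * p), n, p)
    beta_true <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- x %*% beta_true + rnorm(n)
    alpha <- runif(1, 0.1, 1)
    lam <- runif(1, 0.01, 0.5)
    fit <- elasticNetFit(x, y, alpha, lam, tol = 1e-18)
    expect_lt(kktCheck(x, y, alpha, lam, fit$beta)$max_violation, 1e-6)
  }
})

test_that("fits agree with glmnet as an independent reference", {
  skip_if_not_installed("glmnet")
  set.seed(104)
  n <- 100; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  y <- x %*% c(rep(1.5, 3), rep(0, p - 3)) + rnorm(n)
  # glmnet standardizes the response internally, which rescales the ridge
  # part of the penalty; on a unit-variance response the two objectives
  # coincide exactly, making this a clean independent check
  s <- sqrt(mean((y - mean(y))^2))
  ys <- as.numeric(y) / s
  for (alpha in c(0.5, 1)) {
    lam <- 0.1
    mine <- elasticNetFit(x, ys, alpha, lam, tol = 1e-18)
    # give glmnet a path ending at lam (its single-lambda fits are
    # approximate)
    path <- exp(seq(log(1), log(lam), length.out = 30))
    gf <- glmnet::glmnet(x, ys, alpha = alpha, lambda = path,
                         standardize = TRUE, thresh = 1e-14)
    gb <- as.numeric(gf$beta[, 30])
    expect_lt(max(abs(mine$beta - gb)), 1e-6)
    expect_lt(abs(mine$intercept - gf$a0[30]), 1e-6)
  }
})

test_that("lambda grid is log-spaced down from the all-zero threshold", {
  set.seed(105)
  x <- matrix(rnorm(50 * 8), 50, 8)
  y <- x[, 1] + rnorm(50)
  g <- makeLambdaGrid(x, y, alpha = 0.5, nLambda = 30)
  expect_length(g, 30)
  # the largest penalty yields the all-zero model, by construction
  f <- elasticNetFit(x, y, 0.5, g[1])
  expect_true(all(f$beta == 0))
  expect_equal(f$intercept, mean(y))
  # a slightly smaller penalty activates at least one coefficient
  f2 <- elasticNetFit(x, y, 0.5, g[1] * 0.99)
  expect_gt(sum(f2$beta != 0), 0)
  # log-spacing: constant consecutive ratios
  expect_lt(diff(range(g[-1] / g[-length(g)])), 1e-10)
  expect_identical(makeLambdaGrid(x, y, 0.5, nLambda = 1),
                   makeLambdaGrid(x, y, 0.5, nLambda = 30)[1])
  expect_error(makeLambdaGrid(x, y, alpha = 0), "explicit grid")
})

test_that("sparsity is non-increasing along the descending path", {
  set.seed(106)
  x <- matrix(rnorm(80 * 30), 80, 30)
  y <- x %*% rnorm(30) + rnorm(80)
  g <- makeLambdaGrid(x, y, 0.5, nLambda = 40)
  fit <- elasticNetFit(x, y, 0.5, g)
  nnz <- colSums(fit$beta != 0)
  # descending lambda -> growing support, allowing the rare single-step
  # wobble of exact coordinate descent near support changes
  drops <- -pmin(diff(nnz), 0)
  expect_lte(sum(drops), 2)
  expect_lte(max(drops), 1)
  expect_gte(nnz[length(nnz)], nnz[1])
  expect_gt(cor(seq_along(nnz), nnz, method = "spearman"), 0.9)
})

test_that("cross-validation selects deterministically with larger-lambda ties", {
  set.seed(107)
  x <- matrix(rnorm(60 * 10), 60, 10)
  y <- x[, 1] * 2 + rnorm(60)
  g <- makeLambdaGrid(x, y, 0.5, nLambda = 25)
  cv1 <- crossValidate(x, y, 0.5, g, k = 5, seed = 42)
  cv2 <- crossValidate(x, y, 0.5, g, k = 5, seed = 42)
  expect_identical(cv1@cvm, cv2@cvm)
  expect_identical(cv1@lambdaSel, cv2@lambdaSel)
  expect_identical(cv1@cvm[match(cv1@lambdaSel, cv1@lambda)], min(cv1@cvm))
  # grid of length 1: that lambda is selected
  cv3 <- crossValidate(x, y, 0.5, g[5], k = 5, seed = 1)
  expect_identical(cv3@lambdaSel, g[5])
  expect_error(crossValidate(x, y, 0.5, g, k = 100), "folds")
})

test_that("pure-noise response yields a sparse model near the variance floor", {
  cfg <- syntheticConfig(n_samples = 150, n_probes = 300, n_causal = 30,
                         effect_sd = 0, seed = 21)
  bm <- generateCohort(cfg)
  x <- t(betaValues(bm))
  y <- unname(sampleAges(bm))
  g <- makeLambdaGrid(x, y, 0.5, nLambda = 50)
  cv <- crossValidate(x, y, 0.5, g, k = 10, seed = 3)
  fit <- elasticNetFit(x, y, 0.5, cv@lambdaSel)
  expect_lte(sum(fit$beta != 0), ncol(x) / 10)
  expect_lt(min(cv@cvm), 1.1 * var(y))
})

test_that("standardized and raw-scale parameterizations predict identically", {
  set.seed(108)
  x <- matrix(rnorm(70 * 6, mean = 5, sd = 3), 70, 6)
  y <- x[, 2] + rnorm(70)
  fit <- elasticNetFit(x, y, 0.5, 0.1)
  pred_raw <- fit$intercept + x %*% fit$beta
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm, "-")
  xs <- sqrt(colMeans(xc^2))
  pred_std <- mean(y) + sweep(xc, 2, xs, "/") %*% fit$betaStd
  expect_lt(max(abs(pred_raw - pred_std)), 1e-8)
})

test_that("trainClock recovers planted signal and records provenance", {
  bm <- generateCohort(syntheticConfig(n_samples = 150, n_probes = 500,
                                       n_causal = 50, seed = 17))
  sp <- splitTrainTest(bm, 0.2, seed = 2)
  fit <- trainClock(sp$train, nLambda = 40, k = 5, seed = 6)
  expect_s4_class(fit$model, "ClockModel")
  expect_s4_class(fit$cv, "CVResult")
  pred <- predictAge(fit$model, sp$test)
  expect_gt(precisionR(pred), 0.85)
  pv <- clockProvenance(fit$model)
  expect_identical(pv$alpha, 0.5)
  expect_identical(pv$n_train, 120L)
  expect_identical(pv$age_unit, "years")
  expect_identical(sort(names(pv$probe_means)),
                   sort(names(clockCoefficients(fit$model))))
  # missing betas are mean-imputed without derailing training
  b <- betaValues(sp$train)
  b[sample(length(b), 200)] <- NA
  tr2 <- toy_beta_set(b, ages = sampleAges(sp$train))
  fit2 <- trainClock(tr2, nLambda = 20, k = 5, seed = 6)
  expect_gt(length(clockCoefficients(fit2$model)), 0)
})

test_that("degenerate training inputs are refused", {
  bm <- generateCohort(syntheticConfig(n_samples = 30, n_probes = 50,
                                       seed = 1))
  const <- toy_beta_set(betaValues(bm), ages = rep(40, 30))
  expect_error(trainClock(const, nLambda = 10, k = 5), "constant age")
  expect_error(trainClock(bm[, 1:10], nLambda = 10, k = 5), "at least 20")
})

test_that("training in days scales coefficients but predicts in years", {
  bm <- generateCohort(syntheticConfig(n_samples = 120, n_probes = 200,
                                       n_causal = 40, seed = 19))
  sp <- splitTrainTest(bm, 0.25, seed = 4)
  fy <- trainClock(sp$train, nLambda = 30, k = 5, seed = 5,
                   ageUnit = "years")
  fd <- trainClock(sp$train, nLambda = 30, k = 5, seed = 5,
                   ageUnit = "days")
  py <- predictAge(fy$model, sp$test)
  pd <- predictAge(fd$model, sp$test)
  # the day-scale clock is the exact 365.25-fold rescaling of the
  # year-scale fit, and predictions always come back in years
  expect_equal(pd$dnam_age, py$dnam_age, tolerance = 1e-12)
  expect_equal(clockProvenance(fd$model)$lambda,
               clockProvenance(fy$model)$lambda * 365.25, tolerance = 1e-12)
  expect_equal(clockCoefficients(fd$model),
               clockCoefficients(fy$model) * 365.25, tolerance = 1e-12)
})
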