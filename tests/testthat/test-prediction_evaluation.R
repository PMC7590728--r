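test_that("predictAge computes the exact linear rule", {
  bm <- toy_beta_set(matrix(c(0.5, 0.2, 0.8, 0.4), 2,
                            dimnames = list(c("cgA", "cgB"), c("s1", "s2"))),
                     ages = c(30, 40))
  m <- ClockModel(30, c(cgA = 10))
  pred <- predictAge(m, bm)
  expect_equal(pred$dnam_age, c(30 + 10 * 0.5, 30 + 10 * 0.8))
  expect_equal(pred$residual, pred$dnam_age - pred$chronological_age)

  # intercept-only clock predicts the intercept everywhere
  m0 <- ClockModel(52.5)
  expect_equal(predictAge(m0, bm)$dnam_age, c(52.5, 52.5))

  # probe order and non-clock probes are irrelevant
  perm <- bm[c(2, 1), ]
  expect_equal(predictAge(m, perm)$dnam_age, pred$dnam_age)

  # exact linearity of the model term in the betas
  m2 <- ClockModel(5, c(cgA = 4, cgB = -2))
  half <- toy_beta_set(betaValues(bm) / 2, ages = c(30, 40))
  full_term <- predictAge(m2, bm)$dnam_age - 5
  half_term <- predictAge(m2, half)$dnam_age - 5
  expect_equal(half_term, full_term / 2)
})

test_that("missing clock CpGs are resolved per policy", {
  bm <- toy_beta_set(matrix(c(0.5, 0.2), 1,
                            dimnames = list("cgA", c("s1", "s2"))),
                     ages = c(30, 40))
  m <- ClockModel(10, c(cgA = 2, cgZ = 100),
                  provenance = list(probe_means = c(cgA = 0.5, cgZ = 0.25)))
  expect_error(predictAge(m, bm, missingPolicy = "error"), "cgZ")
  pm <- predictAge(m, bm, missingPolicy = "impute_stored_means")
  expect_equal(pm$dnam_age, 10 + 2 * c(0.5, 0.2) + 100 * 0.25)
  ph <- predictAge(m, bm, missingPolicy = "impute_half")
  expect_equal(ph$dnam_age, 10 + 2 * c(0.5, 0.2) + 100 * 0.5)
  # NA cells are governed by the same policy
  b <- betaValues(bm); b[1, 2] <- NA
  bm_na <- toy_beta_set(b, ages = c(30, 40))
  m1 <- ClockModel(10, c(cgA = 2),
                   provenance = list(probe_means = c(cgA = 0.5)))
  expect_error(predictAge(m1, bm_na, missingPolicy = "error"), "cgA")
  expect_equal(predictAge(m1, bm_na,
                          missingPolicy = "impute_stored_means")$dnam_age,
               10 + 2 * c(0.5, 0.5))
})

test_that("MAD is the median absolute prediction error", {
  expect_equal(accuracyMAD(toy_pred(c(31, 29, 33), c(30, 30, 30))), 1)
  expect_equal(accuracyMAD(toy_pred(c(30, 30), c(30, 30))), 0)
  # even n: midpoint of the two central order statistics
  expect_equal(accuracyMAD(toy_pred(c(32, 26), c(30, 30))), 3)
  # permutation invariance
  set.seed(1)
  pr <- toy_pred(rnorm(20, 50, 5), rnorm(20, 50, 5))
  expect_equal(accuracyMAD(pr[sample(20), ]), accuracyMAD(pr))
  expect_error(accuracyMAD(pr[0, ]), "empty")
})

test_that("precision r follows the product-moment formula", {
  expect_equal(precisionR(toy_pred(c(20, 30, 40), c(20, 30, 40))), 1)
  # pure offset leaves precision at 1 (accuracy, not precision, suffers)
  expect_equal(precisionR(toy_pred(c(22, 32, 42), c(20, 30, 40))), 1)
  # 4-point hand-computable series against the textbook formula
  x <- c(1, 2, 4, 8); y <- c(2, 3, 5, 7)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(precisionR(toy_pred(y, x)), r_oracle, tolerance = 1e-12)
  expect_error(precisionR(toy_pred(c(5, 5, 5), c(1, 2, 3))), "constant")
  expect_error(precisionR(toy_pred(c(1, 2), c(1, 2))), "at least 3")
})

test_that("Fisher Z transform and inverse are exact", {
  expect_identical(fisherZ(0), 0)
  for (r in c(-0.9, 0.5, 0.99))
    expect_equal(fisherZInverse(fisherZ(r)), r, tolerance = 1e-12)
  expect_equal(fisherZ(0.95), atanh(0.95), tolerance = 1e-12)
  expect_equal(fisherZ(0.95), 1.8318, tolerance = 1e-4)
  expect_error(fisherZ(1), "\\|r\\| < 1")
  expect_error(fisherZ(-1.2), "\\|r\\| < 1")
})

test_that("bootstrap interval behaves on degenerate and clean data", {
  # perfectly collinear: interval collapses to [1, 1] at the Z cap
  pr <- toy_pred(2 * (1:20) + 5, 1:20)
  ci <- bootstrapRCI(pr, nBoot = 50, seed = 3)
  expect_equal(ci$lower, 1, tolerance = 1e-9)
  expect_equal(ci$upper, 1, tolerance = 1e-9)

  set.seed(204)
  x <- runif(200, 20, 80)
  y <- x + rnorm(200, sd = 6)
  pr2 <- toy_pred(y, x)
  ci2 <- bootstrapRCI(pr2, nBoot = 500, seed = 7)
  expect_identical(bootstrapRCI(pr2, nBoot = 500, seed = 7)$lower, ci2$lower)
  r_hat <- precisionR(pr2)
  expect_lt(ci2$lower, r_hat)
  expect_gt(ci2$upper, r_hat)
  expect_lt(ci2$upper - ci2$lower, 0.1)
  expect_error(bootstrapRCI(pr2[1:5, ]), "at least 10")
})

test_that("high-precision cohort gives a narrow Fisher-Z interval", {
  # n = 200 with true r near 0.95
  set.seed(205)
  x <- runif(200, 20, 80)
  sd_noise <- sd(x) * sqrt(1 / 0.95^2 - 1)
  y <- x + rnorm(200, sd = sd_noise)
  pr <- toy_pred(y, x)
  ci <- bootstrapRCI(pr, nBoot = 1000, seed = 11)
  expect_lt(ci$upper - ci$lower, 0.04)
})

test_that("linear EAA is exactly centred and age-orthogonal", {
  set.seed(206)
  x <- runif(80, 20, 70)
  pr <- toy_pred(x + rnorm(80, sd = 3) + 2, x)
  for (method in c("linear", "smoothing_spline", "piecewise_cubic")) {
    perfect <- suppressWarnings(
      computeEAA(toy_pred(seq(20, 80, length.out = 30),
                          seq(20, 80, length.out = 30)), method = method))
    expect_lt(max(abs(eaaValues(perfect))), 1e-8)
  }
  e <- computeEAA(pr, method = "linear")
  expect_lt(abs(mean(eaaValues(e))), 1e-10)
  expect_lt(abs(e@diagnosticCor), 1e-10)
  # explicit normal-equations oracle for the calibration line
  fit <- lm(pr$dnam_age ~ pr$chronological_age)
  oracle <- pr$dnam_age - (coef(fit)[1] + coef(fit)[2] * pr$chronological_age)
  expect_equal(unname(eaaValues(e)), unname(oracle), tolerance = 1e-10)
})

test_that("spline calibration removes old-age flattening bias", {
  set.seed(207)
  x <- runif(400, 20, 88)
  true_dnam <- ifelse(x <= 65, x, 65 + 0.3 * (x - 65))  # saturating bias
  pr <- toy_pred(true_dnam + rnorm(400, sd = 1.5), x)
  lin <- computeEAA(pr, method = "linear")
  spl <- computeEAA(pr, method = "smoothing_spline")
  pw <- computeEAA(pr, method = "piecewise_cubic", knot = 65)
  # whole-sample correlation is 0 for OLS by construction; the bias lives
  # in the flattened stratum, where the spline must remove the trend
  old <- x > 65
  cor_old <- function(e) abs(cor(eaaValues(e)[old], x[old]))
  expect_gt(cor_old(lin), 0.3)
  expect_lt(cor_old(spl), cor_old(lin))
  expect_lt(cor_old(pw), cor_old(lin))
  # the spline's own diagnostic stays near zero
  expect_lt(abs(spl@diagnosticCor), 0.05)
})

test_that("knot outside the age range warns but fits", {
  pr <- toy_pred(seq(30, 45, length.out = 20) + rnorm(20, sd = 0.5),
                 seq(30, 45, length.out = 20))
  expect_warning(computeEAA(pr, method = "piecewise_cubic", knot = 70),
                 "outside")
})

test_that("reverse-direction calibration is available and sign-consistent", {
  set.seed(208)
  x <- runif(60, 20, 70)
  pr <- toy_pred(x + rnorm(60, sd = 2), x)
  fwd <- computeEAA(pr, method = "linear")
  rev <- computeEAA(pr, method = "linear", direction = "age_on_dnam")
  # both orientations agree on who is epigenetically old
  expect_gt(cor(eaaValues(fwd), eaaValues(rev)), 0.9)
})

test_that("group comparison matches a hand-computed Welch test", {
  e <- new("EAAResult",
           eaa = setNames(c(1.0, 2.0, 3.0, 2.5, 3.5, 4.5),
                          sprintf("s%d", 1:6)),
           method = "linear", knot = NA_real_, diagnosticCor = 0)
  groups <- c(rep("ref", 3), rep("cmp", 3))
  gc <- compareGroupsEAA(e, groups, reference = "ref")
  a <- c(2.5, 3.5, 4.5); b <- c(1.0, 2.0, 3.0)
  expect_equal(gc$mean_difference, mean(a) - mean(b), tolerance = 1e-12)
  # textbook Welch statistic and Welch-Satterthwaite df
  se2 <- var(a) / 3 + var(b) / 3
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(gc$p_value, p_oracle, tolerance = 1e-10)
  expect_true(gc$ci[1] <= gc$mean_difference &
                gc$mean_difference <= gc$ci[2])

  # identical multisets: zero difference
  e2 <- new("EAAResult", eaa = setNames(rep(c(1, 2, 3), 2), sprintf("t%d", 1:6)),
            method = "linear", knot = NA_real_, diagnosticCor = 0)
  gc2 <- compareGroupsEAA(e2, groups, reference = "ref")
  expect_equal(gc2$mean_difference, 0)

  expect_error(compareGroupsEAA(e, c("a", "a", "b", "b", "c", "c"), "a"),
               "two groups")
})
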