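#' Apply an epigenetic clock to a cohort
#'
#' Predicted DNAm age of sample `j` is the clock intercept plus the
#' linear combination `sum_i beta_ij * w_i` over the clock CpGs —
#' probes not in the clock are ignored, so predictions do not depend on
#' the presence or order of non-clock probes. Clock CpGs absent from
#' the cohort (or observed as `NA`) are resolved by `missingPolicy`:
#' `"error"` refuses and lists the ids, `"impute_stored_means"`
#' substitutes the training-set probe means stored in the model
#' provenance, `"impute_half"` substitutes 0.5. Predictions are
#' reported in years regardless of the clock's training age unit.
#'
#' @param model a [ClockModel-class].
#' @param bm a [BetaSet-class].
#' @param missingPolicy one of `"error"`, `"impute_stored_means"`,
#'   `"impute_half"`.
#' @return A prediction data.frame with columns `sample_id`,
#'   `dnam_age`, `chronological_age`, `residual` (`dnam_age -
#'   chronological_age`), all ages in years.
#' @export
predictAge <- function(model, bm,
                       missingPolicy = c("error", "impute_stored_means",
                                         "impute_half")) {
  missingPolicy <- match.arg(missingPolicy)
  validObject(model)
  cf <- clockCoefficients(model)
  n <- ncol(bm)
  if (length(cf)) {
    ids <- names(cf)
    present <- ids %in% probeIds(bm)
    vals <- matrix(NA_real_, length(cf), n,
                   dimnames = list(ids, sampleIds(bm)))
    if (any(present))
      vals[present, ] <- betaValues(bm)[ids[present], , drop = FALSE]
    if (anyNA(vals)) {
      if (missingPolicy == "error") {
        bad <- ids[rowSums(is.na(vals)) > 0]
        stop("clock CpG(s) unresolvable in the matrix: ",
             paste(head(bad, 10), collapse = ", "),
             if (length(bad) > 10) sprintf(" and %d more", length(bad) - 10)
             else "")
      }
      fill <- if (missingPolicy == "impute_half") {
        setNames(rep(0.5, length(cf)), ids)
      } else {
        pm <- clockProvenance(model)$probe_means
        if (is.null(pm)) stop("model provenance has no stored probe means")
        bad <- setdiff(ids[rowSums(is.na(vals)) > 0], names(pm))
        if (length(bad))
          stop("no stored mean for clock CpG(s): ",
               paste(head(bad, 10), collapse = ", "))
        pm[ids]
      }
      na_ix <- which(is.na(vals), arr.ind = TRUE)
      vals[na_ix] <- fill[na_ix[, 1L]]
    }
    dnam <- clockIntercept(model) + as.numeric(crossprod(vals, cf))
  } else {
    dnam <- rep(clockIntercept(model), n)
  }
  unit <- clockProvenance(model)$age_unit
  if (!is.null(unit) && identical(unit, "days")) dnam <- dnam / .DAYS_PER_YEAR
  chron <- unname(sampleAges(bm))
  data.frame(sample_id = sampleIds(bm), dnam_age = dnam,
             chronological_age = chron, residual = dnam - chron,
             stringsAsFactors = FALSE)
}

#' Accuracy: median absolute prediction error (MAD)
#'
#' The MAD of an epigenetic clock, in the convention of the clock
#' literature: the median over samples of `|dnam_age -
#' chronological_age|` in years (for even n, the mean of the two
#' central order statistics) — not the dispersion-around-median
#' statistic.
#'
#' @param pred a prediction data.frame from [predictAge()].
#' @return MAD in years.
#' @export
accuracyMAD <- function(pred) {
  if (nrow(pred) < 1) stop("empty prediction")
  median(abs(pred$residual))
}

#' Precision: Pearson correlation of DNAm age with chronological age
#'
#' @param pred a prediction data.frame from [predictAge()].
#' @return Pearson r.
#' @export
precisionR <- function(pred) {
  if (nrow(pred) < 3) stop("need at least 3 samples")
  if (sd(pred$dnam_age) == 0 || sd(pred$chronological_age) == 0)
    stop("correlation undefined for a constant series")
  cor(pred$dnam_age, pred$chronological_age)
}

#' Fisher's Z transform and its inverse
#'
#' `fisherZ(r) = 0.5 * log((1 + r) / (1 - r)) = artanh(r)`, the
#' variance-stabilizing transform of a correlation;
#' `fisherZInverse(z) = tanh(z)`.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @param z transformed value(s).
#' @return transformed values.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("fisherZ requires |r| < 1")
  atanh(r)
}

#' @rdname fisherZ
#' @export
fisherZInverse <- function(z) tanh(z)

.Z_CAP <- atanh(1 - 1e-12)

#' Bootstrap confidence interval for the precision r
#'
#' Resamples samples with replacement, computes r per replicate, and
#' forms a percentile interval on the Fisher-Z scale before
#' back-transforming. Degenerate resamples (either series constant) are
#' redrawn and counted; replicate r values of magnitude 1 are capped at
#' `artanh(1 - 1e-12)` on the Z scale. Deterministic given `seed`.
#'
#' @param pred a prediction data.frame from [predictAge()], n >= 10.
#' @param nBoot bootstrap replicates, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed integer RNG seed.
#' @return list with `lower`, `upper`, `level`, `nBoot`, `redraws`.
#' @export
bootstrapRCI <- function(pred, nBoot = 1000, level = 0.95, seed = 1L) {
  n <- nrow(pred)
  if (n < 10) stop("need at least 10 samples for a bootstrap interval")
  x <- pred$chronological_age
  y <- pred$dnam_age
  redraws <- 0L
  rs <- .with_seed(seed, vapply(seq_len(nBoot), function(b) {
    repeat {
      ix <- sample.int(n, n, replace = TRUE)
      if (sd(x[ix]) > 0 && sd(y[ix]) > 0) return(cor(x[ix], y[ix]))
      redraws <<- redraws + 1L
    }
  }, numeric(1)))
  z <- pmin(pmax(atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12)), -.Z_CAP), .Z_CAP)
  qs <- quantile(z, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(lower = tanh(qs[1]), upper = tanh(qs[2]), level = level,
       nBoot = nBoot, redraws = redraws)
}

#' Summarize clock performance on a cohort
#'
#' Bundles the precision (Pearson r with its Fisher-Z bootstrap
#' interval), accuracy (MAD in years), and the regression of DNAm age
#' on chronological age (the dotted calibration line of the standard
#' scatter plot).
#'
#' @param pred a prediction data.frame from [predictAge()].
#' @param nBoot,level,seed bootstrap controls, see [bootstrapRCI()].
#' @return list of class `clock_evaluation` with fields `r`, `r_ci`,
#'   `mad`, `n`, `regression_slope`, `regression_intercept`.
#' @export
evaluateClock <- function(pred, nBoot = 1000, level = 0.95, seed = 1L) {
  fit <- lm(dnam_age ~ chronological_age, data = pred)
  structure(list(r = precisionR(pred),
                 r_ci = bootstrapRCI(pred, nBoot = nBoot, level = level,
                                     seed = seed),
                 mad = accuracyMAD(pred), n = nrow(pred),
                 regression_slope = unname(coef(fit)[2]),
                 regression_intercept = unname(coef(fit)[1])),
            class = "clock_evaluation")
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat(sprintf("Clock evaluation (n = %d)\n", x$n))
  cat(sprintf("  precision r: %.4f [%.4f, %.4f] (%.0f%% bootstrap CI)\n",
              x$r, x$r_ci$lower, x$r_ci$upper, 100 * x$r_ci$level))
  cat(sprintf("  accuracy MAD: %.3f years\n", x$mad))
  cat(sprintf("  DNAm age ~ age: slope %.3f, intercept %.2f\n",
              x$regression_slope, x$regression_intercept))
  invisible(x)
}

#' Epigenetic age acceleration with calibration
#'
#' EAA is the residual of DNAm age after regressing it on chronological
#' age. The calibration curve is fit by ordinary least squares
#' (`"linear"`), by a truncated-power cubic with one knot (continuous
#' second derivative, `"piecewise_cubic"`), or by a cubic smoothing
#' spline with smoothness chosen by generalized cross-validation
#' (`"smoothing_spline"`). The non-linear methods absorb systematic
#' age-dependent bias (e.g. under-prediction in the oldest samples) so
#' that EAA is not a function of age. `direction = "age_on_dnam"` fits
#' the reverse regression (calibrating chronological age on DNAm age)
#' and defines EAA as predicted minus observed chronological age; the
#' default direction follows the standard residual definition.
#'
#' @param pred a prediction data.frame from [predictAge()].
#' @param method `"linear"`, `"smoothing_spline"`, or
#'   `"piecewise_cubic"`.
#' @param knot knot position in years for the piecewise cubic, default
#'   70; a knot outside the observed age range triggers a warning and
#'   the fit proceeds.
#' @param direction regression direction, see Details.
#' @return An [EAAResult-class].
#' @export
computeEAA <- function(pred, method = c("linear", "smoothing_spline",
                                        "piecewise_cubic"),
                       knot = 70, direction = c("dnam_on_age",
                                                "age_on_dnam")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  n <- nrow(pred)
  if (method != "linear" && n < 10)
    stop("spline calibration needs at least 10 samples")
  if (direction == "dnam_on_age") {
    xv <- pred$chronological_age; yv <- pred$dnam_age
  } else {
    xv <- pred$dnam_age; yv <- pred$chronological_age
  }
  eaa <- switch(method,
    linear = residuals(lm(yv ~ xv)),
    piecewise_cubic = {
      if (knot < min(xv) || knot > max(xv))
        warning("knot at ", knot,
                " years lies outside the observed age range")
      h <- pmax(xv - knot, 0)
      residuals(lm(yv ~ xv + I(xv^2) + I(xv^3) + I(h^3)))
    },
    smoothing_spline = {
      ss <- smooth.spline(xv, yv, cv = FALSE)
      yv - predict(ss, xv)$y
    })
  eaa <- as.numeric(eaa)
  if (direction == "age_on_dnam") eaa <- -eaa
  names(eaa) <- pred$sample_id
  dc <- if (sd(eaa) > 0) cor(eaa, pred$chronological_age) else 0
  new("EAAResult", eaa = eaa, method = method,
      knot = if (method == "piecewise_cubic") knot else NA_real_,
      diagnosticCor = dc)
}

#' Compare epigenetic age acceleration between two groups
#'
#' Welch's unequal-variance two-sample test of the mean EAA difference
#' (comparison minus reference) with a 95% confidence interval.
#'
#' @param eaa an [EAAResult-class].
#' @param groups per-sample group labels, aligned with the EAA samples
#'   (or named by sample id); exactly two labels must be present, each
#'   with at least 3 samples.
#' @param reference the reference group label.
#' @param level confidence level, default 0.95.
#' @return list of class `group_comparison` with fields `reference`,
#'   `comparison`, `mean_difference` (years), `ci`, `p_value`, `test`.
#' @export
compareGroupsEAA <- function(eaa, groups, reference, level = 0.95) {
  v <- eaaValues(eaa)
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[names(v)]
  if (length(groups) != length(v))
    stop("groups must align with the EAA samples")
  labs <- unique(groups)
  if (length(labs) != 2)
    stop("exactly two groups required (got ", length(labs),
         "); compare pairs of groups separately")
  if (!reference %in% labs) stop("reference label not present")
  comparison <- setdiff(labs, reference)
  a <- v[groups == comparison]
  b <- v[groups == reference]
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 samples")
  tt <- t.test(a, b, var.equal = FALSE, conf.level = level)
  structure(list(reference = reference, comparison = comparison,
                 mean_difference = unname(mean(a) - mean(b)),
                 ci = unname(tt$conf.int), p_value = tt$p.value,
                 test = "Welch two-sample t-test"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("EAA difference %s - %s: %+.3f years [%.3f, %.3f], p = %.3g (%s)\n",
              x$comparison, x$reference, x$mean_difference, x$ci[1], x$ci[2],
              x$p_value, x$test))
  invisible(x)
}
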