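#' Geometric grid of training-set sizes
#'
#' Learning-curve designs space training sizes geometrically — dense at
#' small n where performance changes fast, sparse near the full cohort:
#' `size_k = round(nMin * (nFull/nMin)^(k/nSteps))` for
#' `k = 0 ... nSteps-1`, with plain nearest-integer rounding (half away
#' from zero, not banker's rounding). With `(100, 2227, 14)` this
#' yields 100, 125, 156, 194, 243, 303, 378, 472, 589, 735, 918, 1145,
#' 1430, 1784.
#'
#' @param nMin smallest size, `0 < nMin < nFull`.
#' @param nFull full training-set size (not itself included in the
#'   grid).
#' @param nSteps number of sizes, at least 2.
#' @return strictly increasing integer vector; duplicates arising from
#'   rounding over tiny ranges are removed with a warning.
#' @export
geometricSizeGrid <- function(nMin, nFull, nSteps) {
  if (nMin <= 0 || nMin >= nFull) stop("need 0 < nMin < nFull")
  if (nSteps < 2) stop("nSteps must be at least 2")
  k <- seq_len(nSteps) - 1
  sizes <- as.integer(floor(nMin * (nFull / nMin)^(k / nSteps) + 0.5))
  if (anyDuplicated(sizes)) {
    warning("rounding produced duplicate sizes; de-duplicated")
    sizes <- unique(sizes)
  }
  sizes
}

#' Design of a subsampling experiment
#'
#' @param sizes ascending training-set sizes (e.g. from
#'   [geometricSizeGrid()]).
#' @param replicates random training subsets per size, default 5.
#' @param probeSets subset of `c("epic_all", "common_450k")`:
#'   `"epic_all"` uses all autosomal probes, `"common_450k"` only the
#'   autosomal probes shared between EPIC and 450K.
#' @param baseSeed integer; each (size, replicate) cell derives its own
#'   seed deterministically from it, so cells are reproducible
#'   independently of execution order.
#' @return list of class `subsample_design`.
#' @export
subsampleDesign <- function(sizes, replicates = 5,
                            probeSets = c("epic_all", "common_450k"),
                            baseSeed = 1L) {
  probeSets <- match.arg(probeSets, several.ok = TRUE)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be ascending")
  if (replicates < 1) stop("replicates must be at least 1")
  structure(list(sizes = as.integer(sizes),
                 replicates = as.integer(replicates),
                 probeSets = probeSets, baseSeed = as.integer(baseSeed)),
            class = "subsample_design")
}

# deterministic per-cell seed, independent of execution order
.cell_seed <- function(baseSeed, size, replicate) {
  as.integer((abs(as.numeric(baseSeed)) %% 65536 * 1000003 +
                as.numeric(size) * 10007 +
                as.numeric(replicate) * 101) %% 2147483629)
}

#' Run the probe-set / sample-size comparison experiment
#'
#' For each (size, replicate) cell a simple random subject subset of
#' the full training set is drawn with a seed derived from the design's
#' base seed; the *same* subset is used for every probe set within the
#' cell (paired design). For each probe set, the training probes are
#' restricted (`"epic_all"`: autosomes; `"common_450k"`: autosomal
#' 450K/EPIC-shared probes), a clock is trained via [trainClock()], and
#' precision (r) and accuracy (MAD) are measured on the fixed test set.
#'
#' @param fullTrain,test disjoint [BetaSet-class] cohorts; probe flags
#'   must be present.
#' @param design a [subsampleDesign()].
#' @param trainParams named list overriding [trainClock()] defaults
#'   (`alpha`, `k`, `nLambda`, `minRatio`, `tol`, `maxit`).
#' @return data.frame of records with columns `size`, `replicate`,
#'   `probe_set`, `r`, `mad`, `n_cpgs`, `seed`, `subset_hash` (a hash
#'   of the subject subset certifying pairing across probe sets).
#' @seealso [summarizeWithSplines()], [comparePlatforms()]
#' @export
runSubsampleExperiment <- function(fullTrain, test, design,
                                   trainParams = list()) {
  if (!inherits(design, "subsample_design"))
    stop("design must be a subsampleDesign()")
  if (length(intersect(sampleIds(fullTrain), sampleIds(test))))
    stop("training and test samples must be disjoint")
  n <- ncol(fullTrain)
  if (max(design$sizes) > n)
    stop("largest size (", max(design$sizes),
         ") exceeds the full training set (", n, ")")
  tp <- utils::modifyList(list(alpha = 0.5, k = 10, nLambda = 100,
                               minRatio = 1e-4, tol = 1e-7, maxit = 1e5),
                          trainParams)
  restricted <- lapply(setNames(design$probeSets, design$probeSets),
                       function(ps) switch(ps,
                         epic_all = restrictToAutosomes(fullTrain),
                         common_450k = restrictToCommon(fullTrain)))
  rows <- list()
  for (size in design$sizes) {
    for (rep_i in seq_len(design$replicates)) {
      seed <- .cell_seed(design$baseSeed, size, rep_i)
      idx <- sort(.with_seed(seed, sample(n, size)))
      subset_hash <- sum(idx * seq_along(idx)) %% 2147483629
      for (ps in design$probeSets) {
        tr <- restricted[[ps]][, idx]
        fit <- trainClock(tr, alpha = tp$alpha, k = tp$k,
                          nLambda = tp$nLambda, minRatio = tp$minRatio,
                          probeSetTag = ps, seed = seed,
                          tol = tp$tol, maxit = tp$maxit)
        pred <- predictAge(fit$model, test,
                           missingPolicy = "impute_stored_means")
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, replicate = rep_i, probe_set = ps,
          r = precisionR(pred), mad = accuracyMAD(pred),
          n_cpgs = length(clockCoefficients(fit$model)),
          seed = seed, subset_hash = subset_hash,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.fit_z_spline <- function(size, z, evalSizes) {
  nd <- length(unique(size))
  if (nd >= 4) {
    kk <- min(10L, nd)
    fit <- mgcv::gam(z ~ s(size, k = kk),
                     data = data.frame(size = size, z = z))
    pr <- predict(fit, newdata = data.frame(size = evalSizes), se.fit = TRUE)
  } else {
    warning("fewer than 4 distinct sizes: falling back to a linear fit")
    fit <- lm(z ~ size, data = data.frame(size = size, z = z))
    pr <- predict(fit, newdata = data.frame(size = evalSizes), se.fit = TRUE)
  }
  data.frame(size = evalSizes, fit = as.numeric(pr$fit),
             lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
             upper = as.numeric(pr$fit + 1.96 * pr$se.fit))
}

#' Spline-smoothed learning curves for the subsampling experiment
#'
#' For each probe set, fits a cubic smoothing spline (smoothness by
#' generalized cross-validation, via `mgcv`) of the Fisher-Z
#' transformed r values on training size, forms pointwise `+/- 1.96 *
#' SE` bands, and inverse-transforms curve and bands with `tanh`; MAD
#' curves use the same spline machinery without transformation. The
#' summaries are a pure function of the records: re-summarizing a
#' serialized record table reproduces the curves exactly.
#'
#' @param records record data.frame from [runSubsampleExperiment()] (or
#'   re-read from its serialized TSV).
#' @param evalPoints number of evaluation points spanning the observed
#'   size range, default 100.
#' @return named list, one entry per probe set, each holding data.frames
#'   `r` and `mad` with columns `size`, `fit`, `lower`, `upper`.
#' @export
summarizeWithSplines <- function(records, evalPoints = 100) {
  stopifnot(all(c("size", "probe_set", "r", "mad") %in% colnames(records)))
  out <- list()
  for (ps in unique(records$probe_set)) {
    rec <- records[records$probe_set == ps, ]
    evalSizes <- seq(min(rec$size), max(rec$size), length.out = evalPoints)
    rcap <- pmin(pmax(rec$r, -1 + 1e-12), 1 - 1e-12)
    zsum <- .fit_z_spline(rec$size, atanh(rcap), evalSizes)
    rsum <- within(zsum, {
      fit <- tanh(fit); lower <- tanh(lower); upper <- tanh(upper)
    })
    msum <- .fit_z_spline(rec$size, rec$mad, evalSizes)
    out[[ps]] <- list(r = rsum, mad = msum)
  }
  out
}

#' Paired probe-set differences across training sizes
#'
#' Per (size, replicate) cell, the difference `epic_all - common_450k`
#' in precision and accuracy, with per-size means and t-based 95%
#' confidence intervals over replicates. Requires paired records: both
#' probe sets present for every cell with identical subject subsets.
#'
#' @param records record data.frame from [runSubsampleExperiment()].
#' @return list with data.frames `perCell` (`size`, `replicate`,
#'   `delta_r`, `delta_mad`) and `perSize` (`size`, `mean_delta_r`,
#'   CI bounds, `mean_delta_mad`, CI bounds).
#' @export
comparePlatforms <- function(records) {
  a <- records[records$probe_set == "epic_all", ]
  b <- records[records$probe_set == "common_450k", ]
  if (!nrow(a) || !nrow(b))
    stop("both probe sets must be present")
  m <- merge(a, b, by = c("size", "replicate"),
             suffixes = c("_epic", "_common"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b))
    stop("unpaired records: every (size, replicate) cell needs both probe sets")
  if ("subset_hash_epic" %in% colnames(m) &&
      any(m$subset_hash_epic != m$subset_hash_common))
    stop("unpaired records: subject subsets differ across probe sets")
  perCell <- data.frame(size = m$size, replicate = m$replicate,
                        delta_r = m$r_epic - m$r_common,
                        delta_mad = m$mad_epic - m$mad_common)
  perCell <- perCell[order(perCell$size, perCell$replicate), ]
  rownames(perCell) <- NULL
  ci <- function(v) {
    mu <- mean(v)
    if (length(v) < 2 || sd(v) == 0) return(c(mu, mu, mu))
    half <- stats::qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
    c(mu, mu - half, mu + half)
  }
  perSize <- do.call(rbind, lapply(split(perCell, perCell$size), function(d) {
    cr <- ci(d$delta_r); cm <- ci(d$delta_mad)
    data.frame(size = d$size[1], mean_delta_r = cr[1],
               delta_r_lower = cr[2], delta_r_upper = cr[3],
               mean_delta_mad = cm[1], delta_mad_lower = cm[2],
               delta_mad_upper = cm[3])
  }))
  rownames(perSize) <- NULL
  list(perCell = perCell, perSize = perSize[order(perSize$size), ])
}
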