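#' @import methods
#' @importFrom stats coef cor lm median predict quantile residuals rnorm runif
#'   sd setNames t.test var smooth.spline rbeta fitted
#' @importFrom utils head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @useDynLib epiclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.SEX_CHROMOSOMES <- c("X", "Y")
.AUTOSOMES <- as.character(1:22)
.INTERCEPT_TOKEN <- "(Intercept)"
.DAYS_PER_YEAR <- 365.25

#' BetaSet: methylation beta values with sample and probe annotation
#'
#' `BetaSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' container moved between every stage of the clock pipeline. Rows are CpG
#' probes, columns are samples. The `"beta"` assay holds methylation beta
#' values (fraction methylated, in `[0, 1]`, `NA` permitted); an optional
#' `"detectionP"` assay of identical shape holds per-cell detection p-values.
#'
#' Column data must provide `sample_id`, `age` (chronological age in years,
#' positive and finite), `sex` (`female`/`male`/`unknown`), `group`
#' (ancestry/cohort label) and `batch`. Row data must provide `cpg_id`,
#' `chromosome` (`1`..`22`, `X`, `Y`), `design_type` (`I`/`II`) and the
#' logical probe flags `cross_hybridizing`, `snp_proximal`, `on_450k`,
#' `on_epic`.
#'
#' @aliases BetaSet-class
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

.REQUIRED_SAMPLE_COLS <- c("sample_id", "age", "sex", "group", "batch")
.REQUIRED_PROBE_COLS <- c("cpg_id", "chromosome", "design_type",
                          "cross_hybridizing", "snp_proximal",
                          "on_450k", "on_epic")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  cd <- colData(object)
  rd <- rowData(object)
  miss_s <- setdiff(.REQUIRED_SAMPLE_COLS, colnames(cd))
  if (length(miss_s))
    msg <- c(msg, paste0("colData lacks: ", paste(miss_s, collapse = ", ")))
  miss_p <- setdiff(.REQUIRED_PROBE_COLS, colnames(rd))
  if (length(miss_p))
    msg <- c(msg, paste0("rowData lacks: ", paste(miss_p, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "sample_ids are not unique")
    if (anyDuplicated(rd$cpg_id))
      msg <- c(msg, "cpg_ids are not unique")
    if (ncol(object) > 0) {
      age <- cd$age
      if (any(!is.finite(age)) || any(age <= 0))
        msg <- c(msg, "all ages must be finite and > 0")
    }
    bad_chr <- setdiff(unique(as.character(rd$chromosome)),
                       c(.AUTOSOMES, .SEX_CHROMOSOMES))
    if (length(bad_chr))
      msg <- c(msg, paste0("invalid chromosome labels: ",
                           paste(bad_chr, collapse = ", ")))
    b <- assay(object, "beta")
    rng <- suppressWarnings(range(b, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "beta values outside [0, 1]")
    if ("detectionP" %in% assayNames(object)) {
      dp <- assay(object, "detectionP")
      rngp <- suppressWarnings(range(dp, na.rm = TRUE))
      if (is.finite(rngp[1]) && (rngp[1] < 0 || rngp[2] > 1))
        msg <- c(msg, "detection p-values outside [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta values, probes in rows, samples in
#'   columns. Dimnames are taken from the metadata ids.
#' @param sampleMeta `data.frame` with one row per sample; see
#'   [BetaSet-class] for the required columns.
#' @param probeMeta `data.frame` with one row per probe.
#' @param detectionP optional matrix of detection p-values, same shape as
#'   `beta`.
#' @return A [BetaSet-class] object.
#' @examples
#' bm <- BetaSet(matrix(runif(6), 3, 2,
#'                      dimnames = list(paste0("cg", 1:3), c("s1", "s2"))),
#'               sampleMeta = data.frame(sample_id = c("s1", "s2"),
#'                                       age = c(30, 40), sex = "female",
#'                                       group = "ref", batch = "b1"),
#'               probeMeta = data.frame(cpg_id = paste0("cg", 1:3),
#'                                      chromosome = "1", design_type = "II",
#'                                      cross_hybridizing = FALSE,
#'                                      snp_proximal = FALSE,
#'                                      on_450k = TRUE, on_epic = TRUE))
#' @export
BetaSet <- function(beta, sampleMeta, probeMeta, detectionP = NULL) {
  beta <- as.matrix(beta)
  if (nrow(beta) != nrow(probeMeta))
    stop("nrow(beta) must equal nrow(probeMeta)")
  if (ncol(beta) != nrow(sampleMeta))
    stop("ncol(beta) must equal nrow(sampleMeta)")
  dimnames(beta) <- list(as.character(probeMeta$cpg_id),
                         as.character(sampleMeta$sample_id))
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    if (!identical(dim(detectionP), dim(beta)))
      stop("detectionP must have the same shape as beta")
    dimnames(detectionP) <- dimnames(beta)
    assays$detectionP <- detectionP
  }
  se <- SummarizedExperiment(
    assays = assays,
    colData = DataFrame(sampleMeta, row.names = colnames(beta)),
    rowData = DataFrame(probeMeta, row.names = rownames(beta)))
  new("BetaSet", se)
}

#' A sparse linear epigenetic clock
#'
#' An epigenetic clock is a sparse linear predictor of chronological age:
#' the predicted DNAm age of a sample is the clock intercept plus the
#' weighted sum of the sample's beta values at the clock CpGs. `provenance`
#' records how the clock was trained (elastic-net mixing `alpha`, selected
#' penalty `lambda`, training-set size, probe-set tag, fold seed, age unit,
#' and the training-set probe means used for imputation at prediction
#' time).
#'
#' @slot intercept numeric scalar, years.
#' @slot coefficients named numeric vector, years per unit beta; no entry
#'   is zero and names (CpG ids) are unique.
#' @slot provenance list of training metadata.
#' @aliases ClockModel-class
#' @export
setClass("ClockModel",
         representation(intercept = "numeric", coefficients = "numeric",
                        provenance = "list"),
         prototype(intercept = 0, coefficients = setNames(numeric(0),
                                                          character(0)),
                   provenance = list()))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  cf <- object@coefficients
  if (length(cf)) {
    if (is.null(names(cf)) || any(!nzchar(names(cf))))
      msg <- c(msg, "coefficients must be named by CpG id")
    else if (anyDuplicated(names(cf)))
      msg <- c(msg, "coefficient CpG ids must be unique")
    if (any(!is.finite(cf)))
      msg <- c(msg, "coefficients must be finite")
    if (any(cf == 0))
      msg <- c(msg, "stored coefficients must be nonzero")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ClockModel-class
#' @param intercept,coefficients,provenance see slots.
#' @export
ClockModel <- function(intercept, coefficients = setNames(numeric(0),
                                                          character(0)),
                       provenance = list()) {
  coefficients <- coefficients[coefficients != 0]
  new("ClockModel", intercept = as.numeric(intercept),
      coefficients = coefficients, provenance = provenance)
}

#' Cross-validation result for an elastic-net penalty path
#'
#' @slot lambda descending positive penalty grid.
#' @slot cvm per-lambda mean squared error across folds.
#' @slot cvsd per-lambda standard error (sd of fold MSEs / sqrt(k)).
#' @slot lambdaSel the penalty minimizing `cvm`; ties go to the larger
#'   (more penalized) lambda.
#' @slot k fold count.
#' @slot foldSeed seed used for the fold assignment.
#' @aliases CVResult-class
#' @export
setClass("CVResult",
         representation(lambda = "numeric", cvm = "numeric", cvsd = "numeric",
                        lambdaSel = "numeric", k = "integer",
                        foldSeed = "integer"))

setValidity("CVResult", function(object) {
  msg <- character()
  if (length(object@cvm) != length(object@lambda))
    msg <- c(msg, "cvm and lambda lengths differ")
  if (length(object@lambda) && is.unsorted(rev(object@lambda), strictly = FALSE))
    msg <- c(msg, "lambda grid must be descending")
  if (length(object@lambdaSel) == 1L && length(object@cvm)) {
    if (!object@lambdaSel %in% object@lambda)
      msg <- c(msg, "lambdaSel not in grid")
    else if (abs(object@cvm[match(object@lambdaSel, object@lambda)] -
                 min(object@cvm)) > 1e-12 * max(1, min(object@cvm)))
      msg <- c(msg, "cvm at lambdaSel is not the minimum")
  }
  if (length(msg)) msg else TRUE
})

#' Quality-control report
#'
#' Bookkeeping for probe/sample exclusions: per-criterion excluded-probe
#' counts (a probe failing several criteria is counted once per criterion,
#' so the counts may sum to more than the number of removed probes), the
#' surviving probe count, and excluded sample ids with reasons.
#'
#' @slot nInput,nSurviving probe counts before/after.
#' @slot excludedByCriterion named integer vector of per-criterion counts.
#' @slot excludedProbes character vector of removed probe ids.
#' @slot excludedSamples named character vector, reason keyed by sample id.
#' @slot details list of extra diagnostics (e.g. missingness tables).
#' @aliases QCReport-class
#' @export
setClass("QCReport",
         representation(nInput = "integer", nSurviving = "integer",
                        excludedByCriterion = "integer",
                        excludedProbes = "character",
                        excludedSamples = "character", details = "list"),
         prototype(nInput = 0L, nSurviving = 0L,
                   excludedByCriterion = setNames(integer(0), character(0)),
                   excludedProbes = character(0),
                   excludedSamples = setNames(character(0), character(0)),
                   details = list()))

setValidity("QCReport", function(object) {
  msg <- character()
  if (any(object@excludedByCriterion < 0))
    msg <- c(msg, "criterion counts must be non-negative")
  removed <- object@nInput - object@nSurviving
  if (length(object@excludedByCriterion) &&
      sum(object@excludedByCriterion) < removed)
    msg <- c(msg, "criterion counts sum to less than removed probes")
  if (length(msg)) msg else TRUE
})

#' Epigenetic age acceleration (EAA) for a cohort
#'
#' EAA is the residual of DNAm age after regressing it on chronological
#' age; positive values mark samples epigenetically older than expected
#' for their age. The calibration curve is linear (ordinary least
#' squares), a piecewise cubic with one knot, or a smoothing spline.
#'
#' @slot eaa named numeric vector of per-sample EAA, years.
#' @slot method one of `"linear"`, `"piecewise_cubic"`,
#'   `"smoothing_spline"`.
#' @slot knot knot position in years (piecewise method only, `NA`
#'   otherwise).
#' @slot diagnosticCor Pearson correlation between EAA and chronological
#'   age; exactly 0 (to numerical precision) for the linear method.
#' @aliases EAAResult-class
#' @export
setClass("EAAResult",
         representation(eaa = "numeric", method = "character",
                        knot = "numeric", diagnosticCor = "numeric"))

setMethod("show", "BetaSet", function(object) {
  cat(sprintf("BetaSet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  b <- assay(object, "beta")
  cat(sprintf("  missing beta cells: %d\n", sum(is.na(b))))
  if ("detectionP" %in% assayNames(object))
    cat("  detection p-values: present\n")
  if (ncol(object))
    cat(sprintf("  age range: %.1f-%.1f years\n",
                min(colData(object)$age), max(colData(object)$age)))
  invisible(NULL)
})

setMethod("show", "ClockModel", function(object) {
  cat(sprintf("ClockModel: intercept %.4g years, %d CpG coefficients\n",
              object@intercept, length(object@coefficients)))
  pv <- object@provenance
  if (length(pv)) {
    keys <- intersect(c("alpha", "lambda", "n_train", "probe_set", "age_unit"),
                      names(pv))
    for (k in keys) cat(sprintf("  %s: %s\n", k, format(pv[[k]])))
  }
  invisible(NULL)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold CV over %d lambdas; selected lambda %.6g (CV MSE %.6g)\n",
              object@k, length(object@lambda), object@lambdaSel,
              min(object@cvm)))
  invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d -> %d probes\n", object@nInput,
              object@nSurviving))
  if (length(object@excludedByCriterion)) {
    for (nm in names(object@excludedByCriterion))
      cat(sprintf("  %s: %d\n", nm, object@excludedByCriterion[[nm]]))
  }
  if (length(object@excludedSamples))
    cat(sprintf("  excluded samples: %d\n", length(object@excludedSamples)))
  invisible(NULL)
})

setMethod("show", "EAAResult", function(object) {
  cat(sprintf("EAAResult (%s): n = %d, mean %.3g years, cor with age %.3g\n",
              object@method, length(object@eaa), mean(object@eaa),
              object@diagnosticCor))
  invisible(NULL)
})
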