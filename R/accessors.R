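#' Accessors for BetaSet and ClockModel
#'
#' `betaValues()` returns the probes x samples beta matrix;
#' `detectionP()` the matching detection p-value matrix (or `NULL`);
#' `sampleData()` / `probeData()` the sample and probe annotation as
#' data.frames; `sampleIds()` / `probeIds()` the id vectors;
#' `sampleAges()` the chronological ages in years.
#'
#' @param x a [BetaSet-class] object.
#' @return see details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
betaValues <- function(x) assay(x, "beta")

#' @rdname accessors
#' @export
detectionP <- function(x) {
  if ("detectionP" %in% assayNames(x)) assay(x, "detectionP") else NULL
}

#' @rdname accessors
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @rdname accessors
#' @export
probeData <- function(x) as.data.frame(rowData(x))

#' @rdname accessors
#' @export
sampleIds <- function(x) as.character(colData(x)$sample_id)

#' @rdname accessors
#' @export
probeIds <- function(x) as.character(rowData(x)$cpg_id)

#' @rdname accessors
#' @export
sampleAges <- function(x) {
  setNames(as.numeric(colData(x)$age), sampleIds(x))
}

#' @rdname accessors
#' @param model a [ClockModel-class] object.
#' @export
clockIntercept <- function(model) model@intercept

#' @rdname accessors
#' @export
clockCoefficients <- function(model) model@coefficients

#' @rdname accessors
#' @export
clockProvenance <- function(model) model@provenance

#' @rdname accessors
#' @export
eaaValues <- function(x) x@eaa

#' Ground truth of a synthetic cohort
#'
#' Returns the generator's sidecar for a synthetic [BetaSet-class]: a
#' data.frame of the age-informative (causal) CpG ids and their
#' logit-scale slopes per standardized-age unit. This record is written
#' by [generateCohort()] for recovery tests and is never consulted by
#' training.
#'
#' @param x a [BetaSet-class] produced by [generateCohort()].
#' @return data.frame with columns `cpg_id`, `slope`.
#' @export
cohortTruth <- function(x) {
  tr <- metadata(x)$truth
  if (is.null(tr)) stop("no ground-truth record: not a synthetic cohort?")
  tr
}
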