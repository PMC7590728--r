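.QC_CRITERIA <- c("sex_chromosome", "cross_hybridizing", "detection_p",
                  "snp_proximal")

#' Filter probes by the standard exclusion cascade
#'
#' Removes probes failing any requested criterion: location on a sex
#' chromosome (`sex_chromosome`), the cross-hybridizing flag
#' (`cross_hybridizing`), the SNP-proximal flag (`snp_proximal`), and
#' the detection-p rule (`detection_p`): a probe is removed when the
#' fraction of samples whose detection p-value exceeds
#' `detectionThreshold` is strictly greater than
#' `detectionSampleFraction`. With the default fraction of 0 a single
#' failing cell removes the probe — the strictest reading of "high
#' detection p-value (> 0.01)". The surviving set is independent of the
#' order in which criteria are listed.
#'
#' @param bm a [BetaSet-class].
#' @param criteria subset of
#'   `c("sex_chromosome", "cross_hybridizing", "detection_p",
#'   "snp_proximal")`; empty means no filtering.
#' @param detectionThreshold detection p-value above which a cell fails
#'   (strict inequality), default 0.01.
#' @param detectionSampleFraction tolerated fraction of failing samples
#'   per probe (strict inequality), default 0.
#' @return list with elements `matrix` (filtered [BetaSet-class]) and
#'   `report` ([QCReport-class] with per-criterion counts).
#' @export
filterProbes <- function(bm, criteria = .QC_CRITERIA,
                         detectionThreshold = 0.01,
                         detectionSampleFraction = 0) {
  criteria <- unique(as.character(criteria))
  unknown <- setdiff(criteria, .QC_CRITERIA)
  if (length(unknown))
    stop("unknown criteria: ", paste(unknown, collapse = ", "))
  rd <- probeData(bm)
  p <- nrow(bm)
  fails <- list()
  if ("sex_chromosome" %in% criteria)
    fails$sex_chromosome <- as.character(rd$chromosome) %in% .SEX_CHROMOSOMES
  if ("cross_hybridizing" %in% criteria)
    fails$cross_hybridizing <- as.logical(rd$cross_hybridizing)
  if ("snp_proximal" %in% criteria)
    fails$snp_proximal <- as.logical(rd$snp_proximal)
  if ("detection_p" %in% criteria) {
    dp <- detectionP(bm)
    if (is.null(dp))
      stop("criterion 'detection_p' requested but no detection-p grid present")
    frac_fail <- rowMeans(dp > detectionThreshold, na.rm = TRUE)
    fails$detection_p <- frac_fail > detectionSampleFraction
  }
  counts <- setNames(integer(length(criteria)), criteria)
  for (nm in names(fails)) counts[nm] <- sum(fails[[nm]])
  any_fail <- if (length(fails)) Reduce(`|`, fails) else rep(FALSE, p)
  keep <- !any_fail
  report <- new("QCReport", nInput = p, nSurviving = sum(keep),
                excludedByCriterion = counts,
                excludedProbes = probeIds(bm)[any_fail],
                excludedSamples = setNames(character(0), character(0)),
                details = list(criteria = criteria,
                               detection_threshold = detectionThreshold,
                               detection_sample_fraction = detectionSampleFraction))
  list(matrix = bm[keep, ], report = report)
}

#' Union of per-batch probe exclusions
#'
#' When QC is run per batch, a probe excluded from any one batch is
#' removed from all batches; this returns the set union of the
#' per-batch excluded-probe id sets.
#'
#' @param perBatchExcluded list of character vectors of probe ids.
#' @return sorted character vector of the union.
#' @export
unionBatchExclusions <- function(perBatchExcluded) {
  if (!length(perBatchExcluded)) return(character(0))
  sort(unique(unlist(perBatchExcluded, use.names = FALSE)))
}

#' Restrict to autosomal probes common to EPIC and 450K
#'
#' Keeps exactly the probes with `on_450k & on_epic` on an autosome,
#' preserving probe order — the probe universe of a "common" clock that
#' can be applied to either platform.
#'
#' @param bm a [BetaSet-class].
#' @return the restricted [BetaSet-class].
#' @export
restrictToCommon <- function(bm) {
  rd <- probeData(bm)
  keep <- as.logical(rd$on_450k) & as.logical(rd$on_epic) &
    as.character(rd$chromosome) %in% .AUTOSOMES
  if (!any(keep)) warning("no common autosomal probes remain")
  bm[keep, ]
}

#' Restrict to autosomal probes
#'
#' @param bm a [BetaSet-class].
#' @return the [BetaSet-class] with sex-chromosome probes removed, order
#'   preserved.
#' @export
restrictToAutosomes <- function(bm) {
  keep <- as.character(probeData(bm)$chromosome) %in% .AUTOSOMES
  if (!any(keep)) warning("no autosomal probes remain")
  bm[keep, ]
}

#' Flag samples with extreme epigenetic age acceleration
#'
#' Returns the ids of samples whose absolute EAA strictly exceeds the
#' threshold (default 15 years), the rule used to drop implausible
#' samples before cohort analyses. Expects linearly calibrated EAA.
#'
#' @param eaa an [EAAResult-class].
#' @param eaaThreshold years, default 15.
#' @return character vector of flagged sample ids.
#' @export
excludeOutlierSamples <- function(eaa, eaaThreshold = 15) {
  if (!is(eaa, "EAAResult")) stop("eaa must be an EAAResult")
  v <- eaaValues(eaa)
  names(v)[abs(v) > eaaThreshold]
}
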