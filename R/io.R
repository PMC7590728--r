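#' Read a clock coefficient file
#'
#' Clock coefficient files are comma-separated with header
#' `CpG,Coefficient`. The intercept is stored as the record whose id is
#' the reserved token `(Intercept)`; every other record is a CpG
#' coefficient. Zero-valued coefficient rows are dropped with a warning
#' (a stored zero carries no information for a sparse linear clock).
#' This generic layout can load any published blood-based clock exported
#' in the usual penalized-regression form.
#'
#' @param path file location.
#' @return A [ClockModel-class].
#' @seealso [writeClockCoefficients()], [predictAge()]
#' @export
readClockCoefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE, colClasses = c("character", "character"),
                         strip.white = TRUE)
  if (ncol(tab) < 2)
    stop("coefficient file must have columns (CpG, Coefficient)")
  ids <- tab[[1]]
  wt <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(wt)))
    stop("non-numeric coefficient for id(s): ",
         paste(ids[is.na(wt)], collapse = ", "))
  is_int <- ids == .INTERCEPT_TOKEN
  if (sum(is_int) == 0L)
    stop("no '(Intercept)' record in coefficient file")
  if (sum(is_int) > 1L)
    stop("multiple '(Intercept)' records in coefficient file")
  cpg_ids <- ids[!is_int]
  if (anyDuplicated(cpg_ids))
    stop("duplicate CpG id(s): ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  cf <- setNames(wt[!is_int], cpg_ids)
  nzero <- sum(cf == 0)
  if (nzero) {
    warning(nzero, " zero-valued coefficient row(s) dropped")
    cf <- cf[cf != 0]
  }
  ClockModel(intercept = wt[is_int], coefficients = cf,
             provenance = list(source = path))
}

#' Write a clock coefficient file
#'
#' Writes the `CpG,Coefficient` CSV layout read by
#' [readClockCoefficients()], intercept first, at full double precision
#' (`%.17g`) so that a write/read round trip reproduces every weight
#' bit-exactly.
#'
#' @param model a [ClockModel-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeClockCoefficients <- function(model, path) {
  validObject(model)
  cf <- clockCoefficients(model)
  lines <- c("CpG,Coefficient",
             sprintf("%s,%.17g", .INTERCEPT_TOKEN, clockIntercept(model)),
             if (length(cf)) sprintf("%s,%.17g", names(cf), unname(cf)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write coefficient file: ", path)
  invisible(path)
}

.read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", ""),
                                  data.table = FALSE, showProgress = FALSE))
}

.as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  toupper(as.character(x)) %in% c("TRUE", "T", "1", "YES")
}

#' Read a beta matrix with its metadata companions
#'
#' The on-disk layout is a TSV trio: the matrix file has samples as rows
#' and probes as columns with first column `sample_id`; the companion
#' files carry one row per sample (`sample_id`, `age`, `sex`, `group`,
#' `batch`) and one row per probe (`cpg_id`, `chromosome`,
#' `design_type`, `cross_hybridizing`, `snp_proximal`, `on_450k`,
#' `on_epic`). An optional detection-p TSV has the same shape as the
#' matrix file. Matrix rows and columns are reordered to metadata order,
#' so the result is independent of on-disk ordering; ids must match the
#' metadata ids as sets. Values outside `[0, 1]` are rejected with the
#' offending cells named.
#'
#' @param path beta matrix TSV.
#' @param sampleMetaPath,probeMetaPath companion metadata TSVs.
#' @param detectionPPath optional detection p-value TSV.
#' @return A [BetaSet-class].
#' @export
readBetaMatrix <- function(path, sampleMetaPath, probeMetaPath,
                           detectionPPath = NULL) {
  smeta <- .read_tsv(sampleMetaPath)
  pmeta <- .read_tsv(probeMetaPath)
  miss_s <- setdiff(.REQUIRED_SAMPLE_COLS, colnames(smeta))
  if (length(miss_s))
    stop("sample metadata lacks column(s): ", paste(miss_s, collapse = ", "))
  miss_p <- setdiff(.REQUIRED_PROBE_COLS, colnames(pmeta))
  if (length(miss_p))
    stop("probe metadata lacks column(s): ", paste(miss_p, collapse = ", "))
  for (cc in c("cross_hybridizing", "snp_proximal", "on_450k", "on_epic"))
    pmeta[[cc]] <- .as_logical_col(pmeta[[cc]])
  pmeta$chromosome <- as.character(pmeta$chromosome)
  smeta$sample_id <- as.character(smeta$sample_id)
  pmeta$cpg_id <- as.character(pmeta$cpg_id)

  grid <- .read_beta_grid(path, smeta$sample_id, pmeta$cpg_id, "beta")
  bad <- which(!is.na(grid) & (grid < 0 | grid > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(head(bad, 10), 1L, function(ix)
      sprintf("(%s, %s)", rownames(grid)[ix[1]], colnames(grid)[ix[2]]))
    stop("beta value(s) outside [0, 1] at ", paste(cells, collapse = ", "),
         if (nrow(bad) > 10) sprintf(" and %d more", nrow(bad) - 10) else "")
  }
  dp <- NULL
  if (!is.null(detectionPPath))
    dp <- t(.read_beta_grid(detectionPPath, smeta$sample_id, pmeta$cpg_id,
                            "detection p"))
  BetaSet(t(grid), sampleMeta = smeta, probeMeta = pmeta, detectionP = dp)
}

# reads samples x probes grid, reorders to (sample_ids, cpg_ids)
.read_beta_grid <- function(path, sample_ids, cpg_ids, what) {
  tab <- .read_tsv(path)
  if (colnames(tab)[1] != "sample_id")
    stop(what, " matrix must have first column 'sample_id'")
  rows <- as.character(tab$sample_id)
  if (!setequal(rows, sample_ids) || anyDuplicated(rows))
    stop(what, " matrix sample ids do not match sample metadata ids")
  cols <- colnames(tab)[-1]
  if (!setequal(cols, cpg_ids) || anyDuplicated(cols))
    stop(what, " matrix probe ids do not match probe metadata ids")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rows
  m[sample_ids, cpg_ids, drop = FALSE]
}

#' Write a BetaSet as the TSV trio
#'
#' Inverse of [readBetaMatrix()]: writes the beta matrix (samples as
#' rows), sample metadata, probe metadata, and, when present, the
#' detection-p grid, into `dir` with the given `prefix`. A synthetic
#' cohort's ground-truth sidecar (causal CpG ids and slopes) is written
#' alongside as `<prefix>_truth.tsv`.
#'
#' @param bm a [BetaSet-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix, default `"cohort"`.
#' @return named character vector of the written paths, invisibly.
#' @export
writeBetaMatrix <- function(bm, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix, ".tsv"))
  wr <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  grid <- t(betaValues(bm))
  wr(data.frame(sample_id = rownames(grid), grid, check.names = FALSE),
     p("beta"))
  wr(sampleData(bm), p("samples"))
  wr(probeData(bm), p("probes"))
  paths <- c(beta = p("beta"), samples = p("samples"), probes = p("probes"))
  dp <- detectionP(bm)
  if (!is.null(dp)) {
    g <- t(dp)
    wr(data.frame(sample_id = rownames(g), g, check.names = FALSE),
       p("detp"))
    paths <- c(paths, detp = p("detp"))
  }
  tr <- metadata(bm)$truth
  if (!is.null(tr)) {
    wr(tr, p("truth"))
    paths <- c(paths, truth = p("truth"))
  }
  invisible(paths)
}

#' Validate a BetaSet and report data-quality diagnostics
#'
#' Reporting only, never mutating: counts missing cells per probe and
#' per sample, flags all-missing (unusable) probes, and lists duplicate
#' ids and out-of-range values (none when the object came through the
#' readers, which reject them).
#'
#' @param bm a [BetaSet-class].
#' @return A [QCReport-class]; `details` holds `probe_missing` and
#'   `sample_missing` count tables and `unusable_probes`.
#' @export
validateBetaMatrix <- function(bm) {
  b <- betaValues(bm)
  probe_missing <- rowSums(is.na(b))
  sample_missing <- colSums(is.na(b))
  out_of_range <- sum(!is.na(b) & (b < 0 | b > 1))
  unusable <- rownames(b)[probe_missing == ncol(b) & ncol(b) > 0]
  new("QCReport",
      nInput = nrow(b), nSurviving = nrow(b),
      excludedByCriterion = setNames(integer(0), character(0)),
      excludedProbes = character(0),
      excludedSamples = setNames(character(0), character(0)),
      details = list(
        probe_missing = probe_missing,
        sample_missing = sample_missing,
        n_missing = sum(is.na(b)),
        out_of_range = out_of_range,
        duplicate_sample_ids = unique(sampleIds(bm)[duplicated(sampleIds(bm))]),
        duplicate_probe_ids = unique(probeIds(bm)[duplicated(probeIds(bm))]),
        unusable_probes = unusable))
}
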