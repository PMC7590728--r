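# Runs expr under a fixed RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for a synthetic methylation cohort
#'
#' Defines the generative model of [generateCohort()]: an adult cohort
#' with a minority of age-informative ("causal") CpGs whose logit-scale
#' means drift linearly with standardized age, beta-distributed
#' measurement noise, EPIC-only vs 450K-common probe partitions, batch
#' structure, and an optional epigenetic-age shift in a labelled
#' subgroup.
#'
#' Defaults describe an adult peripheral-blood EPIC cohort: age span
#' 18-88 years, beta noise concentration `precision = 50` (sd about 0.07
#' at a half-methylated probe), logit baselines spread with sd 2 so
#' probes cover the methylated/unmethylated range, and 48% of probes
#' flagged EPIC-only (roughly the fraction of EPIC autosomal content
#' absent from 450K). Causal CpGs are placed only among clean autosomal
#' probes so that planted signal survives the standard QC cascade.
#'
#' @param n_samples,n_probes cohort dimensions.
#' @param age_range `(min, max)` chronological age in years.
#' @param age_distribution `"uniform"`, or `"mixture"` for a
#'   two-component mixture of uniforms (70% mass below 46 years,
#'   mimicking a pregnancy cohort plus an older extension).
#' @param n_causal number of age-informative CpGs.
#' @param effect_sd sd of causal logit-scale age slopes, logits per
#'   standardized-age unit.
#' @param baseline_spread sd of logit-scale probe baselines.
#' @param precision beta-noise concentration phi (> 0); observed beta is
#'   `Beta(mu*phi, (1-mu)*phi)` around mean `mu`.
#' @param frac_epic_only fraction of probes on EPIC but not 450K.
#' @param causal_common_fraction fraction of causal CpGs placed in the
#'   450K-common set.
#' @param group_shift_years epigenetic-age offset (years) injected into
#'   the `"shifted"` subgroup; 0 disables the subgroup.
#' @param frac_shifted fraction of samples in the shifted subgroup when
#'   `group_shift_years != 0`.
#' @param batch_count,batch_sd number of batches and sd of per-probe,
#'   per-batch logit offsets.
#' @param detection_fail_rate per-cell probability that the detection
#'   p-value is drawn above 0.01.
#' @param frac_sex_chr,frac_cross_hyb,frac_snp_proximal fractions of
#'   probes on sex chromosomes, flagged cross-hybridizing, and flagged
#'   SNP-proximal.
#' @param seed integer RNG seed; generation is deterministic given the
#'   full configuration.
#' @return A validated `synthetic_config` list.
#' @export
syntheticConfig <- function(n_samples, n_probes,
                            age_range = c(18, 88),
                            age_distribution = c("uniform", "mixture"),
                            n_causal = round(0.05 * n_probes),
                            effect_sd = 0.4,
                            baseline_spread = 2,
                            precision = 50,
                            frac_epic_only = 0.48,
                            causal_common_fraction = 0.5,
                            group_shift_years = 0,
                            frac_shifted = 0.5,
                            batch_count = 1L,
                            batch_sd = 0,
                            detection_fail_rate = 0,
                            frac_sex_chr = 0.025,
                            frac_cross_hyb = 0.05,
                            frac_snp_proximal = 0.02,
                            seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              age_range = as.numeric(age_range),
              age_distribution = age_distribution,
              n_causal = as.integer(n_causal),
              effect_sd = effect_sd, baseline_spread = baseline_spread,
              precision = precision, frac_epic_only = frac_epic_only,
              causal_common_fraction = causal_common_fraction,
              group_shift_years = group_shift_years,
              frac_shifted = frac_shifted,
              batch_count = as.integer(batch_count), batch_sd = batch_sd,
              detection_fail_rate = detection_fail_rate,
              frac_sex_chr = frac_sex_chr,
              frac_cross_hyb = frac_cross_hyb,
              frac_snp_proximal = frac_snp_proximal,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  bad <- function(msg) stop("invalid synthetic configuration: ", msg,
                            call. = FALSE)
  if (cfg$n_samples < 1) bad("n_samples must be positive")
  if (cfg$n_probes < 1) bad("n_probes must be positive")
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_probes)
    bad("n_causal must lie in [0, n_probes]")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] <= 0 ||
      diff(cfg$age_range) <= 0)
    bad("age_range must be (min, max) with 0 < min < max")
  if (cfg$precision <= 0) bad("precision must be > 0")
  rates <- c(frac_epic_only = cfg$frac_epic_only,
             causal_common_fraction = cfg$causal_common_fraction,
             frac_shifted = cfg$frac_shifted,
             detection_fail_rate = cfg$detection_fail_rate,
             frac_sex_chr = cfg$frac_sex_chr,
             frac_cross_hyb = cfg$frac_cross_hyb,
             frac_snp_proximal = cfg$frac_snp_proximal)
  if (any(rates < 0 | rates > 1))
    bad(paste0("rate(s) outside [0, 1]: ",
               paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")))
  if (cfg$effect_sd < 0 || cfg$baseline_spread < 0 || cfg$batch_sd < 0)
    bad("spreads must be non-negative")
  if (cfg$batch_count < 1) bad("batch_count must be >= 1")
  invisible(TRUE)
}

.draw_ages <- function(cfg) {
  n <- cfg$n_samples
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  if (cfg$age_distribution == "uniform") return(runif(n, lo, hi))
  split <- min(max(46, lo + 0.1 * (hi - lo)), hi - 0.1 * (hi - lo))
  young <- runif(n, lo, split)
  old <- runif(n, split, hi)
  ifelse(runif(n) < 0.7, young, old)
}

#' Generate a synthetic beta-value cohort
#'
#' Draws a cohort under the generative model of [syntheticConfig()]:
#' sample ages from the configured distribution, standardized within the
#' cohort to `z`; for causal probe `i` and sample `j`, logit mean
#' `m_ij = mu_i + b_i * z_j` (plus a per-probe batch offset and, for the
#' shifted subgroup, `b_i * shift / sd(age)` so the induced epigenetic
#' age shift equals `group_shift_years` exactly on the generative
#' surface); non-causal probes have `m_ij = mu_i` plus batch offset.
#' Observed `beta_ij ~ Beta(sigma(m_ij)*phi, (1-sigma(m_ij))*phi)` with
#' `sigma` the logistic function. The causal CpG ids and slopes are
#' recorded in `metadata(result)$truth` (see [cohortTruth()]); the
#' result is bit-identical for identical configurations.
#'
#' @param cfg a [syntheticConfig()] object.
#' @return A [BetaSet-class] with a `detectionP` assay and ground-truth
#'   metadata.
#' @export
generateCohort <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) stop("cfg must be a syntheticConfig()")
  .validate_config(cfg)
  .with_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$n_probes
    ages <- .draw_ages(cfg)
    age_sd <- sd(ages); age_mean <- mean(ages)
    z <- if (n > 1 && age_sd > 0) (ages - age_mean) / age_sd else rep(0, n)

    sample_ids <- sprintf("S%04d", seq_len(n))
    batch <- sprintf("batch%d", sample(cfg$batch_count, n, replace = TRUE))
    sex <- sample(c("female", "male"), n, replace = TRUE)
    if (cfg$group_shift_years != 0) {
      group <- ifelse(runif(n) < cfg$frac_shifted, "shifted", "reference")
    } else group <- rep("reference", n)

    cpg_ids <- sprintf("cg%06d", seq_len(p))
    n_sex <- round(cfg$frac_sex_chr * p)
    chromosome <- sample(.AUTOSOMES, p, replace = TRUE)
    if (n_sex > 0) {
      sex_idx <- sample(p, n_sex)
      chromosome[sex_idx] <- sample(.SEX_CHROMOSOMES, n_sex, replace = TRUE)
    }
    cross_hyb <- runif(p) < cfg$frac_cross_hyb
    snp_prox <- runif(p) < cfg$frac_snp_proximal
    design_type <- sample(c("I", "II"), p, replace = TRUE, prob = c(0.16, 0.84))

    clean <- which(chromosome %in% .AUTOSOMES & !cross_hyb & !snp_prox)
    if (length(clean) < cfg$n_causal)
      stop("not enough clean autosomal probes to place ", cfg$n_causal,
           " causal CpGs")
    causal <- sort(sample(clean, cfg$n_causal))

    # 450K/EPIC partition: causal probes split by causal_common_fraction,
    # remaining EPIC-only quota filled from non-causal probes
    on_450k <- rep(TRUE, p)
    n_causal_common <- round(cfg$causal_common_fraction * cfg$n_causal)
    causal_epic_only <- if (cfg$n_causal > n_causal_common)
      sample(causal, cfg$n_causal - n_causal_common) else integer(0)
    on_450k[causal_epic_only] <- FALSE
    target_epic_only <- round(cfg$frac_epic_only * p)
    remaining <- target_epic_only - length(causal_epic_only)
    noncausal <- setdiff(seq_len(p), causal)
    if (remaining > 0 && length(noncausal))
      on_450k[sample(noncausal, min(remaining, length(noncausal)))] <- FALSE

    mu <- rnorm(p, 0, cfg$baseline_spread)
    slope <- numeric(p)
    slope[causal] <- rnorm(cfg$n_causal, 0, cfg$effect_sd)

    # logit-scale means, probes x samples
    m <- matrix(mu, p, n) + outer(slope, z)
    if (cfg$group_shift_years != 0 && age_sd > 0) {
      dz <- cfg$group_shift_years / age_sd
      shifted <- group == "shifted"
      if (any(shifted))
        m[, shifted] <- m[, shifted] + outer(slope, rep(dz, sum(shifted)))
    }
    if (cfg$batch_sd > 0 && cfg$batch_count > 1) {
      boff <- matrix(rnorm(p * cfg$batch_count, 0, cfg$batch_sd),
                     p, cfg$batch_count)
      m <- m + boff[, match(batch, sprintf("batch%d", seq_len(cfg$batch_count)))]
    }

    mu_beta <- stats::plogis(m)
    phi <- cfg$precision
    beta <- matrix(rbeta(p * n, mu_beta * phi, (1 - mu_beta) * phi), p, n)
    eps <- 1e-6
    beta <- pmin(pmax(beta, eps), 1 - eps)

    detp <- matrix(runif(p * n, 0, 0.005), p, n)
    if (cfg$detection_fail_rate > 0) {
      fails <- runif(p * n) < cfg$detection_fail_rate
      detp[fails] <- runif(sum(fails), 0.011, 1)
    }

    bm <- BetaSet(
      beta,
      sampleMeta = data.frame(sample_id = sample_ids, age = ages, sex = sex,
                              group = group, batch = batch,
                              stringsAsFactors = FALSE),
      probeMeta = data.frame(cpg_id = cpg_ids, chromosome = chromosome,
                             design_type = design_type,
                             cross_hybridizing = cross_hyb,
                             snp_proximal = snp_prox,
                             on_450k = on_450k, on_epic = TRUE,
                             stringsAsFactors = FALSE),
      detectionP = detp)
    metadata(bm)$truth <- data.frame(cpg_id = cpg_ids[causal],
                                     slope = slope[causal],
                                     stringsAsFactors = FALSE)
    metadata(bm)$generator <- list(config = unclass(cfg),
                                   age_mean = age_mean, age_sd = age_sd,
                                   logit_baseline = setNames(mu, cpg_ids),
                                   logit_slope = setNames(slope, cpg_ids))
    bm
  })
}

#' Split a cohort into training and test sets
#'
#' Draws a simple random, disjoint, exhaustive partition of the samples;
#' the probe set is unchanged and the split is deterministic given
#' `seed`.
#'
#' @param bm a [BetaSet-class].
#' @param testFraction proportion of samples assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, both [BetaSet-class].
#' @export
splitTrainTest <- function(bm, testFraction, seed = 1L) {
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  n <- ncol(bm)
  n_test <- max(1L, min(n - 1L, round(n * testFraction)))
  idx <- .with_seed(seed, sample(n, n_test))
  list(train = bm[, setdiff(seq_len(n), idx)], test = bm[, sort(idx)])
}
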