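# Small in-code fixtures shared across test files.

# A fully controllable toy BetaSet. Defaults: clean autosomal probes on
# both platforms, ages 20..(20+n-1).
toy_beta_set <- function(beta, chromosome = NULL, cross_hyb = NULL,
                         snp_prox = NULL, on_450k = NULL, ages = NULL,
                         detectionP = NULL, group = NULL) {
  p <- nrow(beta); n <- ncol(beta)
  pm <- data.frame(
    cpg_id = if (is.null(rownames(beta))) sprintf("cg%03d", seq_len(p))
             else rownames(beta),
    chromosome = if (is.null(chromosome)) rep("1", p) else chromosome,
    design_type = "II",
    cross_hybridizing = if (is.null(cross_hyb)) rep(FALSE, p) else cross_hyb,
    snp_proximal = if (is.null(snp_prox)) rep(FALSE, p) else snp_prox,
    on_450k = if (is.null(on_450k)) rep(TRUE, p) else on_450k,
    on_epic = TRUE, stringsAsFactors = FALSE)
  sm <- data.frame(
    sample_id = if (is.null(colnames(beta))) sprintf("s%03d", seq_len(n))
                else colnames(beta),
    age = if (is.null(ages)) 20 + seq_len(n) - 1 else ages,
    sex = "female",
    group = if (is.null(group)) "ref" else group,
    batch = "b1", stringsAsFactors = FALSE)
  BetaSet(beta, sampleMeta = sm, probeMeta = pm, detectionP = detectionP)
}

# Prediction data.frame straight from dnam/chron vectors.
toy_pred <- function(dnam, chron, ids = NULL) {
  data.frame(sample_id = if (is.null(ids)) sprintf("s%03d", seq_along(dnam))
             else ids,
             dnam_age = dnam, chronological_age = chron,
             residual = dnam - chron, stringsAsFactors = FALSE)
}

# The standard recovery cohort used by training and acceptance tests.
recovery_config <- function(seed = 11L) {
  syntheticConfig(n_samples = 600, n_probes = 3000, n_causal = 150,
                  effect_sd = 0.4, precision = 50, seed = seed)
}
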