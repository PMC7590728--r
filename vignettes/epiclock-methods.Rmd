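---
title: "Building and evaluating epigenetic clocks with epiclock"
author: "epiclock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating epigenetic clocks with epiclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclock)
```

## The model

An epigenetic clock is a sparse linear predictor of chronological age
from DNA-methylation beta values. For sample $j$ with beta values
$X_{ij}$ at CpG $i$,

$$\widehat{\mathrm{age}}_j \;=\; \beta_0 + \sum_{i \in S} X_{ij}\,\beta_i ,$$

where $S$ is a small set of CpGs (typically 1,000--2,000 out of several
hundred thousand) selected, together with the weights, by elastic-net
penalized regression:

$$\min_{\beta_0,\beta}\;\; \frac{1}{2n}\sum_j\Big(y_j - \beta_0 -
x_j^\top\beta\Big)^2 + \lambda\Big(\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big).$$

The mixing parameter is $\alpha = 0.5$ by default; the penalty
$\lambda$ is chosen to minimize the mean squared error under 10-fold
cross-validation on the training set, with ties broken toward the
larger (sparser) penalty. Predictors are standardized to unit
population variance (divisor $n$) before penalization, the response is
centered but not scaled, and coefficients are reported on the raw beta
scale.

Precision is summarized by the Pearson correlation $r$ between
predicted (DNAm) age and chronological age; accuracy by the MAD, the
*median absolute prediction error* in years — the convention of the
clock literature, not the dispersion-around-median statistic.
Epigenetic age acceleration (EAA) is the residual of DNAm age after
regressing it on chronological age.

## The solver

`elasticNetFit()` implements cyclic coordinate descent with
soft-thresholding, warm starts along a descending penalty path, and
sequential strong-rule screening. Screening never changes the answer:
after the candidate set converges, the Karush-Kuhn-Tucker (KKT)
conditions are checked over *all* predictors and any violator joins
the set, repeating until none remain. `kktCheck()` exposes the same
conditions as an independent optimality oracle used by the test suite,
together with two closed forms (ordinary least squares at
$\lambda = 0$, and the univariate soft-threshold solution at
$\alpha = 1$).

Numerical choices worth knowing:

* **Convergence.** A penalty step converges when the largest squared
  coefficient update in a sweep falls below `tol * var(y)`
  (`tol = 1e-7` by default). Scaling the criterion by the response
  variance makes it invariant to the age unit; tests that compare
  against closed forms pass `tol = 1e-18`.
* **Response scale.** The solver minimizes the objective exactly as
  stated for the data given — it does *not* standardize the response
  internally. This matters for the elastic net because the ridge term
  is not invariant to rescaling the response (scaling $y$ by $c$
  scales the squared-error and lasso terms by $c^2$ but the ridge term
  by $c^3$). Reference solvers standardize $y$ internally, which is
  why their day-scale and year-scale age regressions select equivalent
  models. `trainClock(..., ageUnit = "days")` therefore reproduces the
  day-scale convention as the exact 365.25-fold rescaling of the
  year-scale fit, rather than re-solving a (different) optimization
  problem on the day scale.
* **Penalty grid.** 100 log-spaced values from
  $\lambda_{\max} = \max_i |x_i^\top(y-\bar y)|/(n\alpha)$ down to
  $10^{-4}\lambda_{\max}$; $\lambda_{\max}$ is inflated by a relative
  $10^{-9}$ so the top of the grid is all-zero despite floating-point
  rounding. At $\alpha = 0$ no finite penalty zeroes the model and an
  explicit grid must be supplied.
* **Cross-validation folds** are simple random and unstratified, with
  the seed recorded in the model provenance.
* **Missing betas** are imputed with training-set probe means
  (recorded in provenance so prediction can reuse them); all-missing
  probes are dropped with a warning; zero-variance probes receive zero
  coefficients.

## Probe quality control

`filterProbes()` implements the standard exclusion cascade: sex
chromosomes, cross-hybridizing probes, SNP-proximal probes, and the
detection-p rule. Exclusions use strict inequalities (detection
$p > 0.01$ fails; $|\mathrm{EAA}| > 15$ years flags a sample). The
detection rule removes a probe when the fraction of samples with
failing cells strictly exceeds `detectionSampleFraction`; the default
of 0 — any failing cell removes the probe — is the strictest reading
of a "high detection p-value" exclusion, and the fraction is
configurable for laxer per-batch policies. `unionBatchExclusions()`
implements the rule that a probe excluded in any batch is removed from
all batches. `restrictToCommon()` keeps the autosomal CpGs shared
between the EPIC and 450K platforms, the probe universe of a clock
that can be applied to data from either array. Sample-level "low
quality" and PCA-outlier removal are not part of the package: those
procedures are laboratory-specific and not algorithmically defined;
only the $|\mathrm{EAA}|$ rule is implemented
(`excludeOutlierSamples()`).

## The synthetic cohort generator

`generateCohort()` exists so every downstream stage is testable
without access-restricted cohort data. The generative model:

* Ages are drawn uniformly over 18--88 years (or from a two-component
  mixture that mimics a pregnancy cohort plus an older extension) and
  standardized within the cohort to $z_j$.
* Each probe has a logit-scale baseline $\mu_i \sim N(0, 2)$, so
  expected betas cover the methylated/unmethylated range the way array
  probes do.
* A minority of "causal" CpGs receive age slopes
  $b_i \sim N(0, 0.4)$ logits per standardized-age unit; the mean of
  probe $i$ in sample $j$ is $\sigma(\mu_i + b_i z_j)$ with $\sigma$
  the logistic function. Acting on the logit scale keeps means inside
  $(0,1)$ at any age.
* Observed betas are drawn from a beta distribution with that mean and
  concentration $\varphi = 50$ (sd $\approx 0.07$ at a half-methylated
  probe, array-like noise). This respects the $[0,1]$ support;
  Gaussian noise would not.
* 48% of probes are flagged EPIC-only (roughly the fraction of EPIC
  autosomal content absent from 450K); small fractions are placed on
  sex chromosomes (2.5%) or flagged cross-hybridizing (5%) and
  SNP-proximal (2%), matching the order of magnitude of the real
  annotation files. Causal CpGs are placed only among clean autosomal
  probes so planted signal survives QC.
* An optional subgroup "EAA shift" of $s$ years adds
  $b_i \cdot s/\mathrm{sd}(\mathrm{age})$ to every causal probe's
  logit mean in the shifted subgroup — an effective shift of the
  standardized age, so the induced displacement of the generative
  DNAm-age surface equals $s$ exactly (rather than approximately via a
  separately calibrated uniform offset). Batch structure adds
  per-probe, per-batch logit offsets.

The causal CpG ids and slopes are stored as a ground-truth sidecar
(`cohortTruth()`; serialized by `writeBetaMatrix()`), never consulted
by training. What the generator does *not* emulate: probe-type
chemistry differences, cell-composition heterogeneity, genotype
effects on methylation, and realistic correlation structure among
CpGs beyond the shared age signal. Tests passing on synthetic cohorts
therefore certify the *machinery* — selection, fitting, calibration,
bookkeeping — not the biological attainability of any particular
precision on real data.

## EAA calibration

`computeEAA()` offers three calibration curves for the regression of
DNAm age on chronological age: ordinary least squares (`linear`), a
truncated-power cubic with one knot at 70 years (continuous second
derivative; `piecewise_cubic`), and a cubic smoothing spline with
smoothness chosen by generalized cross-validation
(`smoothing_spline`). The non-linear methods matter when a clock
systematically under-predicts in the oldest samples: a straight line
cannot absorb that bias, leaving EAA dependent on age in the old
stratum.

One subtlety the test suite respects: in-sample OLS residuals are
*exactly* orthogonal to the regressor, so the whole-sample Pearson
correlation between linearly calibrated EAA and age is zero by
construction, no matter how biased the clock is. The meaningful
diagnostic of residual age-dependence under old-age flattening is the
EAA-age correlation *within the flattened stratum* (or a non-linear
dependence measure); the package reports the whole-sample correlation
as `diagnosticCor` (it is a useful invariant check), and the tests
compare methods on the old-age stratum.

The calibration direction is DNAm age on chronological age (matching
the definition of EAA as a residual of that regression); the reverse
regression — calibrating chronological age on DNAm age, which some
recalibration discussions propose — is available via
`direction = "age_on_dnam"` and defines EAA as predicted minus
observed chronological age so that signs remain comparable.

Group contrasts (`compareGroupsEAA()`) use Welch's unequal-variance
two-sample test with a 95% confidence interval; the source analyses
do not name their test, and Welch's is the robust default for a
two-group mean comparison.

## The subsampling experiment

`runSubsampleExperiment()` reproduces the probe-set/sample-size
design: training sizes on a geometric grid
(`geometricSizeGrid(100, 2227, 14)` yields 100, 125, ..., 1784 — the
grid is dense at small sizes where learning curves change fastest),
five random training subsets per size, and for each cell two clocks —
one on all autosomal probes, one restricted to the 450K/EPIC-common
set — trained on the *same* subjects (paired design, certified by
recorded subset hashes) and evaluated on one fixed test set. Per-cell
seeds derive deterministically from the base seed, size, and
replicate, so any cell can be recomputed independently and results do
not depend on execution order.

`summarizeWithSplines()` fits smoothing splines (via `mgcv`, with
generalized cross-validation) of the Fisher-Z-transformed $r$ values
on training size, forms pointwise $\pm 1.96\,\mathrm{SE}$ bands, and
back-transforms with $\tanh$ — so curves and bands always stay inside
$(-1, 1)$; MAD curves use the same machinery untransformed. With
fewer than four distinct sizes the summary falls back to a linear fit
with a warning. `comparePlatforms()` reduces the paired records to
per-size mean differences with t-based intervals.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic
cohorts at sizes chosen to exercise every code path while completing
in minutes on a single core: the parameter-recovery cohort has
$n = 600$ samples and $p = 3000$ probes with 150 causal CpGs
($\alpha = 0.5$, 10-fold CV, 100-value penalty grid); the
platform-equivalence experiment uses $p = 2000$ probes, six sizes from
50 to about 400 on the geometric grid, five replicates, a 50-value
grid and 5-fold CV; the group-shift cohort has 1,600 samples and
$p = 1500$, training on 400 reference samples and testing the
injected 0.5-year shift on 400 samples per group. With all causal
CpGs placed in the common probe set, the expected probe-set difference
in precision is zero — the experiment's check is that the paired
$\Delta r$ stays within $\pm 0.02$ at every size while precision rises
steeply with training size.

## Limitations

* The coefficient-file dialect (`CpG,Coefficient` CSV with an
  `(Intercept)` row) is one conventional export of penalized fits;
  published clocks distributed in other layouts need a one-line
  conversion.
* Synthetic cohorts certify machinery, not biology (see above);
  headline precisions from real cohorts are not reproducible here and
  are not claimed.
* Raw intensity processing (iDAT parsing, Noob/BMIQ/functional
  normalization) is out of scope: the pipeline consumes
  already-normalized beta values.
* The smoothing-spline EAA uses `stats::smooth.spline`'s GCV; with
  very few distinct ages the spline can be underdetermined and the
  piecewise-cubic method is the safer choice.
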