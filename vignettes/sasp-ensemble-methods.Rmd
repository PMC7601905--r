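---
title: "Methods: ensemble ridge-Cox SASP scores and their validation"
author: "SASPsurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble ridge-Cox SASP scores and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SASPsurv)
```

## The scientific problem

Cervical cancer cohorts treated with external beam radiotherapy (EBRT),
with or without brachytherapy (BT), show large survival differences by
FIGO stage and treatment. Serum proteins of the senescence-associated
secretory phenotype (SASP) add a third axis: patients with a high
senescence burden have worse disease-specific survival, and — critically —
appear to draw most of the benefit of brachytherapy. `SASPsurv` implements
the full analysis that establishes such a claim from multiplex serum-panel
data: per-protein screening, an ensemble of penalized survival scores,
internal and cross-cohort validation, consensus patient classification, and
stratified treatment-benefit analysis.

The three cohorts the package works with are homogeneous in stage and
treatment: `RTBT2` (stage II, EBRT+BT), `RTBT3` (stage III, EBRT+BT) and
`RT3` (stage III, EBRT only). A `SASPCohort` couples the patients × analytes
log2 concentration matrix with the clinical covariates and the (time, event)
outcome in a `SummarizedExperiment`.

## The penalized score

For a protein panel $x$ (log2 scale), covariates are standardized to zero
mean and unit variance *on the training data*, and the score is the linear
predictor $\eta_i = \beta^\top \tilde{x}_i$ of an L2-penalized Cox model:

$$\hat\beta \;=\; \arg\max_\beta \; \log PL(\beta) \;-\; \tfrac{\lambda}{2}\lVert\beta\rVert_2^2 ,$$

maximized by Newton–Raphson (convergence at max |score| < 1e−8 or 50
iterations, with step-halving), with the Efron correction for tied event
times. Breslow ties are available for cross-checks against other
implementations. The penalty objective is identical to
`survival::coxph(ridge(theta = lambda))`, and equals `glmnet`'s coxnet
parameterization after dividing $\lambda$ by the sample size; both
equalities are asserted in the test suite. At $\lambda = 0$ the fit reduces
to the unpenalized partial-likelihood maximum.

**Why standardize and freeze?** The penalty is only fair across analytes on
a common scale, and a deployed score must be a fixed function of new
measurements. The training center/scale and the cutoff are therefore stored
in the model object and reapplied verbatim — new data are *never*
re-centered, a property asserted as a behavioral contract in the tests.

**Penalty selection.** $\lambda$ is chosen on the training half only, by
k-fold cross-validation (default 10 folds, 50 penalties log-spaced over
$[10^{-3}, 10^3]$), scored by the Verweij–van Houwelingen partial-likelihood
deviance $-2\{\log PL_{full}(\hat\beta_{-k}) - \log PL_{-k}(\hat\beta_{-k})\}$.
Folds are stratified on the event indicator; an assignment leaving a
training set without events is redrawn (at most 10 attempts). On ties the
largest minimizing penalty is taken, favoring shrinkage.

A logistic-outcome variant (penalized logistic regression on the
event-by-horizon indicator) is available through the `family` switch of
`trainModel()`; the proportional-hazards score is the default because the
outcome is censored survival.

## The ensemble procedure

Rather than fitting one model per cohort, the pipeline samples many
event-stratified 50/50 train/test partitions (`sampleSplitPairs`), fits one
score per training half, and keeps the models that replicate:

1. **Dichotomization.** Training scores are cut at the 40th order-statistic
   percentile (`cutoffPercentile = 40`); patients strictly above the cutoff
   are SASP-high. With tie-free scores exactly $\lceil 0.4 n \rceil$
   training patients fall at or below the cutoff; a score exactly equal to
   the cutoff goes to the low group, which preserves "40th percentile" as a
   bound. The score is oriented so the high group has training hazard ratio
   ≥ 1 (coefficients negated when necessary, recorded in the model).
   Cohorts whose high-risk stratum is the top 40% (the RT3-optimized
   models) use `cutoffPercentile = 60`.
2. **Selection.** A model is retained when the SASP-high vs SASP-low Cox
   hazard ratio is at least 3.0 with two-sided Wald p ≤ 0.05 in *both* the
   training and the held-out test half. The published model tables list
   only train/test hazard ratios above 3 at p < 0.05, which is where these
   defaults come from; both are configuration.
3. **Bootstrap validation.** Each retained model is re-evaluated on (by
   default) 1000 subsamples of 70% of the cohort drawn *without*
   replacement; within each subsample the cutoff is re-derived at the
   model's percentile (classical with-replacement resampling is a switch).
   Iterations are binned by p-value (p > 0.05, 0.001 < p ≤ 0.05,
   p ≤ 0.001) and the model passes when at least 95% of iterations reach
   p < 0.05. The asymmetry — cutoff re-derived inside the bootstrap but
   frozen for external validation — follows the procedure as published.
4. **External validation.** The frozen coefficients and cutoff are applied
   unchanged to the independent cohorts; validation on the training cohort
   is refused.

The published description samples 3000 pairs yet reports "1000 different
models"; the two numbers cannot both be hard constraints, so both are
configuration here (`nPairs`, `maxModels`), with `maxModels` capping the
retained models after sorting by bootstrap performance.

Whether the per-model p-values of the published tables are Wald or log-rank
is not stated; the package computes both and reports Wald by default with
the log-rank p alongside.

## Consensus classification and treatment benefit

`buildVoteMatrix` records each model's binary vote per patient;
`consensusVote` derives the plurality label. Two published rules coexist
and both are implemented rather than reconciled: the binary rule
(SASP_H iff > 50% of models vote high) and the ternary rule (H above 75%,
L below 25%, M otherwise). All thresholds are strict, so boundary
fractions fall to the lower tier. Classification confidence is
$\max(f, 1-f)$ for high-vote fraction $f$, and `confidenceSummary` reports
the fraction of patients at or above 75% confidence.

`stratifiedBtEffect` pools the stage III cohorts, labels patients with one
model or with the consensus, and compares omitting vs receiving
brachytherapy inside each SASP stratum (no-BT is the exposed arm, so
HR > 1 means brachytherapy benefit). Per-model p-values are multiplied by
the number of models — an uncapped Bonferroni, chosen because the published
adjusted values exceed 1 (0.052 × 25 = 1.30, 0.338 × 25 = 8.45); a capped
variant and Holm are options. This comparison is observational: treatment
was not randomized and is confounded by indication; the package reproduces
the analysis as designed without causal adjustment.

## Quartile screening conventions

`assignQuartiles` uses linear-interpolation percentiles (`quantile`
type 7) with lower-closed assignment. This convention is not arbitrary: it
is the unique standard percentile definition that reproduces the published
tie-free count pattern 145/144/144/145 for 578 distinct values. Heavy ties
can make quartile counts unequal (they always sum to *n*); all-identical
values are an error. The ensemble's score cutoff, by contrast, uses the
order-statistic (type 1) percentile so that exactly $\lceil p n \rceil$
tie-free training scores fall at or below the cutoff — the two conventions
serve different contracts and are deliberately distinct.

Pooled screening rows adjust for stage (III vs II) and treatment (no-BT vs
BT); within a homogeneous cohort these are constant and omitted. Proteins
with Q4 p < 0.05 anywhere are flagged as panel candidates, with
Holm-adjusted Q4 p-values reported alongside (the exact published
panel-selection rule is not stated; the two published panels are shipped as
presets `p8` and `p7`). Multiplicity correction across the 19 proteins uses
Holm because the published text reports significance "after correcting for
multiple testing" without naming a procedure.

## Luminex preprocessing choices

- **Calibration model**: log2(MFI) regressed on log2(concentration),
  linear by default with a quadratic option — chosen over 4/5-parameter
  logistic curves because both MFI and standard concentrations are log2
  transformed before all statistical analysis in this workflow. The fitted
  curve must be monotone increasing over the standards' range; otherwise it
  is rejected with a warning. Concentrations outside the calibrated MFI
  range are extrapolated but flagged.
- **Replicate CV** uses the sample (n−1) standard deviation
  (CV = sd/mean × 100), appropriate for replicate pairs; groups exceeding
  25% are excluded. CVs are computed over the wells that survive the bead
  filter, which makes the filter idempotent and gives every excluded well
  exactly one primary reason.
- **Bead threshold**: default `minBeads = 35`. The assay's instrument
  setting ("events/bead: 50") is an acquisition target, not a well-level
  QC rule, so the threshold is exposed in configuration.
- **Censoring boundary**: follow-up strictly greater than the horizon is
  censored at the horizon; a time exactly equal to the horizon keeps its
  event status, because censoring applies to follow-up *greater than* 5
  years.
- Whether concentrations or raw MFI feed the survival analysis is left to
  the caller — both are log2 scale and the downstream code is agnostic.

## The synthetic-cohort generator

The generator defines the study conditions under which the pipeline is
exercised and tested. Per patient, a latent senescence factor
$z \sim N(0,1)$ acts twice:

- **Analytes**: $x_{ij} = \mu_j + a_j z_i + \varepsilon_{ij}$,
  $\varepsilon_{ij} \sim N(0, \sigma_j^2)$. Nine prognostic proteins load
  positively ($a_j = 0.8$ on the log2 scale), leptin negatively
  ($a = -0.5$, matching its protective direction), the remaining nine not
  at all. Means default to 10 log2 units, noise to $\sigma_j = 1$, so a
  loaded analyte correlates with $z$ at $0.8/\sqrt{1.64} \approx 0.62$ —
  a strong but not deterministic biomarker, typical of serum panels.
- **Hazard**: event times are exponential given covariates, with linear
  predictor
  $\log 2.3 \cdot [\text{stage III}] + \beta_z z + g(z) [\text{no BT}]$,
  where the no-brachytherapy log hazard ratio interpolates logistically
  from $\log 1.0$ (low senescence) to $\log 3.3$ (high senescence),
  centered at the 60th percentile of $z$ with slope 2 — so the treatment
  effect transitions within roughly one standard deviation around the
  boundary of the top-40% latent stratum, concentrating the benefit of
  brachytherapy in high-senescence patients. The baseline hazard is 0.12
  events/year; loss to follow-up is independent exponential (0.02/year);
  administrative censoring applies at 5 years. `simConfigSignal(h)` sets
  $\beta_z = \log(h)/\Delta$ with $\Delta = E[z \mid \text{top }60\%] -
  E[z \mid \text{bottom }40\%] \approx 1.61$, so the population high/low
  hazard ratio at the 40th-percentile split equals $h$.

Group sizes default to the three cohort sizes (276, 203, 86). Age is
generated (mean 49, sd 10) but carries no hazard — the analysis adjusts for
stage and treatment, not age. Exponential event times were chosen because
they are trivially invertible and sufficient for proportional-hazards
recovery; the generator makes no claim about baseline-hazard shape,
analyte skewness, batch effects, missingness, or informative censoring, so
passing tests demonstrate correctness of the *procedure*, not calibration
to any real cohort. One published inconsistency is left unresolved by
design: quartile tables implying n = 578 versus a reported cohort of 565 —
cohort sizes are configuration, not a constant.

The plate simulator (`simulatePlate`) writes wells on a known monotone
log2–log2 standard curve (default intercept 2, slope 0.9, 4-fold serial
dilutions from 10⁴) with Gaussian log2 noise and Poisson bead counts,
retaining ground-truth concentrations so calibration recovery is testable
exactly in the noiseless limit.

## Numerical and reproducibility choices

- Ridge Newton–Raphson in compiled code with warm starts along the
  descending penalty path; risk-set sums accumulated in one reverse sweep
  with the largest linear predictor factored out of the exponentials for
  stability.
- Monotone likelihood (perfect separation) in the unpenalized Cox fit is
  flagged non-converged with coefficients capped at ±15 on the log scale;
  it cannot occur for $\lambda > 0$.
- Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed by a fixed affine rule modulo
  $2^{31}-1$, so stages can be re-run in isolation. The run manifest
  records per-file MD5 checksums and an overall hash; re-running the same
  configuration and seed reproduces the hash exactly.
- Delimited outputs are written at 6 significant digits, comma-separated,
  UTF-8, header row; exports are byte-stable.

## Problem sizes used by the tests

The test-suite simulations are scaled to desk size as the package's own
choice of test conditions: oracle checks use ≥ 20 instances of ≤ 8 patients
against brute-force risk-set enumeration and grid-search likelihood
maximization (tolerance 1e−4); false-selection control uses 500 split pairs
per seed over 5 seeds on the all-null generator; signal recovery uses 500
pairs and 200 bootstrap iterations at the full RTBT2-like size (n = 276,
high/low hazard ratio 3.5); interaction recovery uses 20 seeds of the
stage III pool (n = 289) with RT3-trained ensembles of 40 pairs. The
Wald/log-rank asymptotic-equivalence property is asserted on the chi-square
statistics (20% relative) with a looser band on the p-values, since ratios
of extreme tail probabilities are numerically unstable even when the
statistics agree.

## Known limitations

- The brachytherapy comparison is confounded by treatment indication; the
  stratified analysis describes, but cannot establish, a causal interaction.
- The generator's single-factor structure cannot probe robustness to
  multiple senescence axes or analyte-specific survival effects beyond the
  latent factor.
- Proportional hazards is assumed throughout; no diagnostics for
  time-varying effects are included.
- Plate-to-plate batch correction and instrument-export parsing are out of
  scope; the preprocessing stage starts from a tidy well table.
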