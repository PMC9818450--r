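---
title: "Methods: transcriptome-wide prognostic screening for censored cohorts"
author: "survscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-wide prognostic screening for censored cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscreen)
```

## The problem

In adult AML treated with intensive chemotherapy followed by
hematopoietic stem-cell transplantation (HSCT), established clinical
predictors — age, white blood cell count, ELN cytogenetic/molecular risk —
leave much of the variation in post-transplant survival unexplained. A
natural question is whether the diagnostic expression level of any single
gene stratifies overall survival *consistently across independent
cohorts*. `survscreen` implements that discovery cascade as a tested,
reusable pipeline, together with a survival-cohort simulator that provides
a fully controlled test bed with known ground truth.

The pipeline has four stages per gene and cohort:

1. **Cutpoint derivation.** The gene's continuous expression is scored
   against survival status at a clinical horizon using the time-dependent
   ROC curve for censored data, and dichotomized at the threshold
   maximizing the Youden index.
2. **Filter gates.** The ROC must show genuine discrimination:
   AUC > 0.5, sensitivity > 0.5 and specificity > 0.5 at the chosen
   cutpoint (all strict).
3. **Cox models.** A univariate Cox proportional-hazards fit on the
   high/low indicator, and a multivariate fit adjusting for age (continuous),
   sex, WBC (continuous), transplant type (allo vs auto) and ELN category;
   both group terms must reach p < 0.05 (two-sided Wald).
4. **Cross-cohort intersection.** A gene is reported only if it passes all
   gates in *every* cohort with the *same* effect direction. The
   intersection — not per-gene multiplicity correction — is the de facto
   false-discovery control; a Benjamini–Hochberg column is reported for
   reference but enters no gate.

## Censored-survival machinery

The survival primitives are implemented from first principles, because the
estimators themselves are the package's core; the `survival` package is
used only as an independent cross-check in the test suite.

**Kaplan–Meier.** Product-limit estimator; the curve steps only at event
times, the median is the earliest time with $\hat S(t) \le 0.5$
(otherwise "not reached").

**Log-rank.** Observed-vs-expected chi-square over pooled event times with
the hypergeometric covariance, for $k \ge 2$ groups. For two groups
without ties it equals the squared Cox score statistic for the group
indicator — an identity the tests verify to $10^{-6}$.

**Cox regression.** Newton–Raphson maximization of the partial likelihood
with the Efron tie correction (Breslow optional), standard errors from the
inverse observed information, per-covariate two-sided Wald tests.
Numerical policy: convergence when the log partial likelihood changes by
less than $10^{-9}$, at most 100 iterations, step-halving on overshoot.
Monotone-likelihood separation (a coefficient drifting beyond $|\beta| >
15$, i.e. hazard ratios beyond $3\times10^6$) sets `converged = FALSE`
rather than returning a silently absurd estimate, and downstream screening
treats such fits as failures. An optional strata term gives each stratum
its own baseline hazard with shared coefficients; the treatment-subgroup
contrast uses it so that the pooled interaction model reparametrizes the
per-arm fits exactly.

**Time-dependent ROC.** Cumulative-cases / dynamic-controls at a fixed
horizon $t$: cases died by $t$, controls remain under observation beyond
$t$. Censoring is handled by inverse-probability-of-censoring weights from
the Kaplan–Meier estimate of the censoring distribution
($w_i = 1/\hat G(T_i^-)$ for cases, $1/\hat G(t)$ for controls); the AUC
is the weighted case–control concordance. With no censoring this reduces
exactly to the Mann–Whitney concordance of marker versus died-by-horizon
status, which is how the tests pin it down; on censored data it agrees
with the Uno estimator in scikit-survival to full precision.

**Horizon.** The default evaluation horizon is 36 months: in this disease
the first three years of follow-up carry nearly all the discriminative
signal, and later horizons leave too few controls. The horizon is a
plain argument/config knob everywhere.

## Cutpoint policy

Candidate thresholds are the observed marker values restricted to the
10th–90th percentile band. The band prevents degenerate splits that would
destabilize the downstream Cox fits; its width is configurable. The
chosen threshold maximizes $J = \text{sens} + \text{spec} - 1$; exact ties
are broken toward the more balanced high/low split and then toward the
smaller cutpoint, making the procedure fully deterministic. "High"
means strictly greater than the cutpoint, so a cutpoint equal to an
observed value is well defined, and the whole partition depends only on
marker ranks (invariant under monotone transforms of expression — which is
also why it does not matter whether a cohort's expression matrix is stored
on the log scale or not).

For secondary endpoints (DFS/EFS) the OS-derived cutpoint is reused by
default, so the secondary analyses evaluate the *same* patient groups; a
toggle derives endpoint-specific cutpoints instead.

Two gate readings are implemented. The default (`strict`) requires the
adjusted group term to reach p < 0.05. The alternative
(`uniThenRetain`) requires univariate significance plus retention — a
converged adjusted fit whose group coefficient keeps the univariate sign —
for users who read "univariate and multivariate regression was computed"
as confirmation rather than a second significance hurdle. Neither reading
is asserted as the original procedure's intent.

## Risk refinement

To refine a categorical risk system (ELN favorable / intermediate /
adverse) with a binary marker, the default mapping shifts marker-high
patients one level toward adverse and leaves marker-low patients in their
base category. The exact recategorization used in published refinements is
rarely specified textually, so the mapping is fully overridable by a
user-supplied (base, marker) → refined table; the default is a declared
interpretation, not a claim. Stratification gain is measured by comparing
log-rank statistics of the base and refined groupings on the identical
sample set.

## The simulator

`simulateCohort()` emulates the structure of portal-derived AML cohorts
without reproducing any real dataset:

- expression: gene-wise standard normal log-intensities (unit SD), so
  planted log hazard ratios are per SD of expression. Planted effects act
  on the *continuous* scale — dichotomization performance is emergent,
  which is the honest way to exercise the cutpoint machinery;
- covariates: age ~ Normal(55, 12) truncated to [18, 80] years; sex
  Bernoulli(0.5); WBC log-normal (median 15 × 10⁹/L, sdlog 0.8);
  transplant allo with probability 0.7 among transplanted patients; ELN
  favorable/intermediate/adverse at 0.25/0.5/0.25;
- survival: Weibull proportional hazards, baseline shape 1.1 and scale 40
  months (baseline median ≈ 29 months — typical of adult AML trial
  cohorts), linear predictor = planted gene terms + confounder terms
  (defaults: age 0.02 per year, male 0.1, WBC 0.004 per unit, allograft
  −0.1, ELN intermediate 0.4, adverse 0.8, continuous covariates centered
  at 55 years and 15 × 10⁹/L) + an optional arm-restricted interaction;
- censoring: administrative (uniform) rather than exponential — cohorts of
  this kind have trial-style follow-up — with the upper bound placed
  between order statistics of $T_i/U_i$ so the realized censored fraction
  hits the target exactly (to rounding by $1/n$). Times are continuous, so
  ties never occur in simulated data;
- determinism: one seed reproduces a cohort bit-identically;
  `simulateCohortSet()` splits a master seed across cohorts.

The default multi-cohort configuration (`trioConfigs()`) uses three
cohorts of 69, 77 and 134 samples with 200 genes, one planted gene at
hazard ratio 2.5 per SD and 35% censoring — the power regime of a typical
three-cohort post-transplant study. What the simulator deliberately does
*not* emulate: realistic expression correlation structure, batch and
platform effects, informative censoring, or ELN categories correlated with
expression. Passing tests therefore demonstrate that the machinery is
correct and well calibrated under proportional hazards, not that any
particular real-data finding is reproducible.

## What the validation suite establishes

Problem sizes were chosen to characterize behaviour at desk scale: 20
replicates of the 200-gene trio for recovery and null calibration, 50
replicates for refinement.

- **Exactness:** Cox coefficients match brute-force grid maximization of
  the explicit partial likelihood on ≤ 12-subject fixtures to $10^{-4}$;
  log-rank equals the squared Cox score to $10^{-6}$; KM matches hand
  product-limit arithmetic; the censored AUC collapses to Mann–Whitney
  concordance without censoring; Fisher and Mann–Whitney group tests
  return exact textbook p-values on the canonical 3 + 3 fixtures.
- **Calibration:** on pure-null trios the single-cohort pass rate is a few
  percent while null genes essentially never survive the three-cohort
  intersection (rate at least ten times lower, usually zero).
- **Power:** a planted hazard-ratio-2.5 gene is recovered by the
  intersection with the correct direction in ≥ 18 of 20 replicates, and
  marker refinement strengthens the base ELN stratification in ≥ 90% of
  replicates.
- **Reproducibility:** a manifest-driven pipeline re-run is byte-identical.
  To make this hold exactly, the pipeline canonicalizes its configuration
  through the same JSON serialization the manifest uses *before*
  computing, so the original run and any re-run consume bit-identical
  parameter values.

## Known limitations

- No time-varying covariates, stratified baseline beyond the treatment
  contrast, penalized Cox, or competing risks.
- The IPCW weights assume censoring independent of the marker; heavily
  marker-dependent censoring would bias the ROC stage.
- Complete-case handling per model: rows missing a covariate are dropped
  from that fit only, with a recorded count; no imputation.
- The screen's per-seed recovery probability under the default trio sizes
  is high but not 1; with cohorts as small as 69 samples, a true
  hazard-ratio-2.5 gene occasionally misses one gate in one cohort — the
  price of demanding unanimity across three small cohorts.
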