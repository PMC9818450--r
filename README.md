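# survscreen

Transcriptome-wide discovery of prognostic expression biomarkers in
right-censored survival cohorts, with the multi-cohort post-transplant AML
setting as the motivating use case.

Given per-cohort expression matrices and clinical tables, the package asks:
*which genes' diagnostic expression stratifies overall survival consistently
across independent cohorts?* For every gene and cohort it

1. derives an optimal dichotomization cutpoint from the time-dependent ROC
   curve for censored survival (cumulative cases / dynamic controls with
   inverse-probability-of-censoring weights, evaluated at a clinical horizon,
   36 months by default), maximizing the Youden index
   *J* = sens + spec − 1 over thresholds in the 10th–90th percentile band;
2. applies filter gates AUC > 0.5, sensitivity > 0.5, specificity > 0.5
   (strict inequalities);
3. fits univariate and confounder-adjusted Cox proportional-hazards models
   (Efron ties, Newton–Raphson, Wald tests) on the high/low indicator —
   adjusting for age, sex, WBC, transplant type and ELN category — and
   requires p < 0.05 for both group terms;
4. intersects the hits across cohorts, keeping only genes that pass every
   gate in **all** cohorts with the **same** effect direction.

A marker that survives can then be used to refine a categorical risk system
(marker-high patients shift one ELN level toward adverse by default) and to
contrast its hazard between treatment arms via a stratified interaction
model. A seeded Weibull proportional-hazards simulator generates
multi-cohort data with planted prognostic genes and known ground truth, so
the whole cascade is testable end to end without any data download.

The survival machinery (Kaplan–Meier, log-rank, Cox partial likelihood,
time-dependent ROC) is implemented from first principles and cross-checked
in the test suite against the `survival` package and classical identities
(log-rank = squared Cox score; censored AUC → Mann–Whitney concordance
without censoring).

## Worked example

Simulate the default three-cohort study (69 / 77 / 134 samples, 200 genes,
one planted gene `G0001` with hazard ratio 2.5 per SD of expression, 35%
censoring), screen every gene in every cohort and intersect:

```r
library(survscreen)

sims    <- simulateCohortSet(trioConfigs(nGenes = 200), masterSeed = 5)
screens <- lapply(sims, function(s) screenCohort(s$cohort, verbose = FALSE))
summary <- intersectCohorts(screens)
summary
#> ScreenSummary: 3 cohorts (cohort1, cohort2, cohort3), horizon 36 months
#>   cohort1: 200 genes screened, 11 pass
#>   cohort2: 200 genes screened, 8 pass
#>   cohort3: 200 genes screened, 8 pass
#>   intersection (consistent direction): 1 gene(s) — G0001
```

Per cohort, a handful of genes clear all five gates by chance or signal;
only the planted gene survives the three-cohort consistency requirement.
Its ledger row in the first cohort:

```r
led <- screenLedger(summary, "cohort1")
led[led$gene_id == "G0001",
    c("auc", "sensitivity", "specificity", "uni_hr", "multi_hr", "multi_p")]
#>     auc sensitivity specificity uni_hr multi_hr   multi_p
#>   0.825       0.503           1   2.90     3.93  0.000287
```

so high expression of `G0001` carries an adjusted hazard ratio of about 3.9
(p ≈ 3e-4) in that cohort — the dichotomized-group effect implied by the
planted per-SD coefficient. The same run, driven by a config file with a
reproducibility manifest and TSV report bundle:

```r
cfg <- system.file("extdata", "demo_trio.yaml", package = "survscreen")
runScreenPipeline(cfg, outDir = "demo_run")
# demo_run/: ledger_<cohort>.tsv, intersection.tsv, km_G0001.tsv,
#            forest_G0001.tsv, refinement_G0001.tsv, manifest.json
rerunFromManifest("demo_run/manifest.json", outDir = "demo_run2")
# byte-identical to demo_run/
```

A thin command-line wrapper with `simulate` / `screen` / `rerun`
subcommands is included at `inst/scripts/survscreen.R`. The methods
vignette (`vignettes/methods.Rmd`) documents the estimators, the gate
logic, the simulator's assumptions and the design decisions.

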