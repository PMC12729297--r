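# hetbatch

Heterogeneity-aware batch correction for gene-expression matrices, and a
testbed for measuring what correction does to biomarker signal.

## The problem

Integrating expression cohorts (microarray or RNA-seq) requires removing
technical batch effects. The standard tool is location-scale empirical-Bayes
correction (ComBat-style): per gene *g* and batch *i*, expression is modelled
as

    Y_ijg = alpha_g + X beta_g + gamma_ig + delta_ig * epsilon_ijg

with an additive batch shift `gamma_ig` and a multiplicative spread factor
`delta_ig`, shrunk across genes via a normal prior on `gamma` and an
inverse-gamma prior on `delta^2`, then removed. This model attributes *all*
systematic between-batch differences to technical noise. In molecularly
heterogeneous diseases such as breast cancer that assumption fails: when two
batches contain different proportions of molecular subtypes (e.g. a
luminal/ER+ fraction of 27.6% in one cohort and 60.5% in the other),
composition-driven expression differences are mistaken for batch effects and
"corrected" away — distorting exactly the biomarkers (ESR1, ERBB2, AURKA) an
integrated analysis cares about.

`hetbatch` implements, from scratch, the EB correction core and four
correction strategies, and quantifies their effect on biomarker fidelity:

| strategy        | what it does |
|-----------------|--------------|
| `parametric`    | plain EB correction, normal/inverse-gamma priors |
| `nonparametric` | EB correction with a Monte-Carlo empirical prior (other genes as weighted donors) |
| `covariate`     | parametric EB with PAM50 subtype protected in the linear model |
| `stratified`    | split by subtype, correct each stratum independently (valid for within-subtype analysis only) |

Fidelity is measured per (biomarker, subtype, batch pair, method): two-sided
Mann–Whitney tests with Holm–Bonferroni adjustment, star labels
(`*` p≤0.05 … `****` p≤0.0001), effect sizes, and a transition label against
the uncorrected baseline — `persisting`, `removed`, `introduced`, `absent`.
A seeded synthetic-data generator reproduces the confounded-composition
scenario with ground truth retained, so estimator recovery and
method-induced distortion are directly measurable. PCA + silhouette
diagnostics summarize global batch/subtype structure.

## Worked example

Simulate two batches of 120 samples whose subtype compositions differ along
the luminal axis (27.6% vs 60.5%) with **zero** true batch effects, run all
four strategies, and test biomarker expression between batches within each
subtype:

```r
library(hetbatch)
cfg <- run_config(preset = "confounded", seed = 11)
res <- run_experiment(cfg)
res$summary
#>         method persisting removed introduced absent skipped
#>     parametric          0       0          1     14       0
#>  nonparametric          0       0          4     11       0
#>      covariate          0       0          0     15       0
#>     stratified          0       0          0     15       0

subset(res$report$cells, !skipped & p_adj <= 0.05 & method != "uncorrected")[,
       c("gene", "subtype", "method", "p_adj", "stars", "transition")]
#>  gene subtype        method        p_adj stars transition
#>  ESR1    LumA    parametric 2.122638e-02     * introduced
#>  ESR1   Basal nonparametric 2.238458e-02     * introduced
#>  ESR1    LumB nonparametric 1.230769e-02     * introduced
#>  ESR1    LumA nonparametric 2.935962e-05  **** introduced
#>  ESR1  Normal nonparametric 3.026634e-02     * introduced
```

There is no batch effect in these data: every starred row is a spurious
within-subtype ESR1 difference *introduced* by subtype-blind correction,
because the ER+-composition imbalance was mistaken for a technical shift.
The subtype-aware strategies introduce none. Over replicates (see
`analysis/05_replicates.R`) the plain strategies average ~0.3 introduced or
persisting significant biomarker cells per run against ~0 for the
subtype-aware ones, and under a fully exchangeable null all four methods
keep the spurious-significance rate at or below the nominal level.

The `analysis/` directory holds the numbered workflow —
`01_simulate.R` → `02_correct.R` → `03_fidelity.R` → `04_diagnostics.R` →
`05_replicates.R` — each a thin driver over the package functions, writing
tables under `results/`.

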