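# expowas

Exposome-wide survival screening and environment-versus-genetics variance
decomposition for large prospective cohorts.

## The problem

Prospective biobanks measure hundreds of correlated environmental,
behavioural and socioeconomic exposures alongside mortality, incident
disease, biomarkers, proteomics and genotypes. Relating that exposome to
aging and premature mortality faces three systematic hazards:

* **reverse causation** — prevalent illness changes behaviour, so an
  exposure can predict death without causing it;
* **residual confounding and redundancy** — strongly intercorrelated
  exposures (income, housing, deprivation, vehicles...) proxy one another;
* **multiplicity** — serial testing of ~10² exposures demands explicit
  false-discovery control with independent replication.

`expowas` implements a multi-stage screening pipeline for this setting,
aimed at epidemiologists and biostatisticians who want each stage as a
tested, configurable R function:

1. **Multiple imputation** of missing exposures by chained random forests
   with predictive mean matching (`impute_cohort()`), pooling all
   downstream estimates by Rubin's rules
   (T = W + (1 + 1/m)·B; `pool_rubin()`, `pool_fisher_z()`).
2. **XWAS screen** (`run_xwas()`): one stratified Cox proportional-hazards
   model per exposure with *age as the timescale* — entry at recruitment
   age (left truncation / delayed entry), strata = 5-year birth cohort ×
   sex, Efron ties — in a stratified 50/50 discovery/replication split with
   Benjamini–Hochberg FDR in each stage; an exposure replicates iff FDR-p
   < 0.05 in both stages with a consistent direction.
3. **Robustness filters**: a poor-health interaction rule for reverse
   causation (remove iff direct p ≥ 0.05 and exposure × poor-health
   interaction p < 0.05), a per-exposure PheWAS with a codified
   two-threshold flag rule for residual confounding, and a proteomic
   age-gap concordance rule (retain iff FDR-significant with the same
   sign as the mortality effect).
4. **Correlation-cluster decomposition**: a heterogeneous correlation
   matrix (Pearson / polyserial / polychoric by pair type, Fisher-z pooled
   across imputed copies), Ward clustering on correlation profiles with a
   within-cluster-sum-of-squares elbow, and one multivariable Cox model
   per cluster after iterative GVIF^(1/(2·df)) > 1.6 pruning; survivors at
   p < 0.05 are the independently associated exposures.
5. **Outcome panels** for the final exposure set: incident diseases
   (prevalent cases excluded), log-transformed sex-specific age-adjusted
   biomarkers, and metabolic risk factors, with FDR within each outcome.
6. **Variance decomposition** (`fit_sequential_models()`): nested Cox
   models M1 (age + sex), M2 (+ PRS quintiles, genotype batch, genetic
   PCs), M3 (+ exposome), M4 (all) on the time-on-study scale, compared by
   explained randomness R² = 1 − exp(−LR/d) and Harrell's C, with Wald-χ²
   importance shares and frozen-coefficient validation on a holdout
   region (`validate_holdout()`).

Because the cohorts such a pipeline targets are access-controlled, the
package ships a **synthetic cohort generator** (`simulate_cohort()`) that
emulates their structure — a blocked Gaussian-copula exposome of mixed
types, Gompertz mortality with 11–15 y administrative follow-up and ~7.3%
deaths, per-disease incidence with PRS effects, a proteomic age-gap
subsample and MAR missingness — with a truth ledger of planted causal
exposures and decoys (income-confounded, reverse-causation,
mortality-only, sign-discordant) so every stage is scored against known
ground truth.

## Worked example

```r
library(expowas)

cfg <- pipeline_config(cohort = cohort_config(n = 20000), seed = 11,
                       stages = c(impute = TRUE, xwas = TRUE, filters = TRUE,
                                  cluster = TRUE, panels = FALSE,
                                  decompose = TRUE))
run <- run_pipeline(cfg)
run
#> XWAS pipeline run (seed 11 ): n = 20000
#>   replicated exposures: 20
#>   filter survivors: 13
#>   clusters: 2 | final exposures: 7

roles <- setNames(run$simulate$truth$role, run$simulate$truth$exposure)
table(roles[run$cluster$final])
#> causal
#>      7
```

Twenty of 42 exposures replicate in the discovery/replication screen (the
planted causal exposures, the 6 decoys, and correlated null block-mates).
The filters remove all 6 decoys, the within-cluster multivariable models
prune the correlated nulls, and the final set is purely causal (7 of the
8 planted effects at this seed; the weakest, log-HR 0.15/SD, misses
replication). The decomposition stage then reports, per outcome, the
pooled R²/C-index of models M1–M4 and the per-category importance:

```r
run$decompose$mortality$fit
#> Sequential decomposition for mortality
#>   model        r2   c_index
#> 1    M1 0.3125606 0.6708654
#> 2    M2 0.3247297 0.6738860
#> 3    M3 0.6168282 0.7608180
#> 4    M4 0.6229395 0.7618395
#> model-4 importance:
#>      group proportion
#> 1      age 0.37307296
#> 2      sex 0.00145519
#> 3      prs 0.01682063
#> 4 exposome 0.60865122
```

Here the exposome adds ~30 R² percentage points over age and sex while
all disease PRS together add under 1 point — the generator's mortality
process is exposome-dominant by construction, and the pipeline reports
exactly that.

`export_summaries(run, "out/")` writes the plot-ready TSVs (volcano,
forest, heat-map matrices, decomposition stack) plus a JSON manifest.

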