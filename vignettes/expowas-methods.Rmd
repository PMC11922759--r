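---
title: "Methods: exposome-wide survival screening and variance decomposition"
author: "expowas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposome-wide survival screening and variance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`expowas` implements a multi-stage exposome-wide analysis of mortality and
aging for prospective cohorts: chained random-forest multiple imputation,
serial Cox screening with discovery/replication FDR control, three
robustness filters (reverse causation, residual confounding, proteomic-age
concordance), correlation-cluster decomposition, outcome panels, and a
nested-model partition of outcome variation between age/sex, polygenic
risk and the exposome. This vignette records the statistical model behind
each stage, the tunable parameters with their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices a maintainer would want justified.

# The screening model

Every screening model is a Cox proportional-hazards model fitted by
partial likelihood with the Efron tie correction. The mortality screen
uses **age as the timescale**: a participant recruited at age $a_0$ who is
followed for $t$ years contributes the risk interval $(a_0, a_0 + t]$, so
the baseline hazard is a function of attained age and recruitment-age
confounding is absorbed nonparametrically. Baseline hazards are further
stratified by 5-year birth cohort crossed with sex (the birth cohort is
`floor((recruit_year - recruit_age)/5)` with the recruitment calendar year
fixed at 2008 by config), and models adjust for assessment centre, years
of education and ethnicity. Left truncation is handled exactly: a subject
enters every risk set only after $a_0$.

Exposure coding: continuous exposures are centred and standardized in the
analysis sample (never recruitment age); ordinal exposures enter as
unstandardized integer scores, i.e. only linear contrasts are tested;
nominal exposures become dummies against the modal reference; binary
exposures enter as 0/1. A per-exposure hook can add extra covariates to a
single exposure's model (the pattern needed when one self-reported
exposure requires an additional health-status adjustment).

The discovery/replication design splits the training region 50/50 with
stratification on the death indicator, applies Benjamini–Hochberg FDR
within each stage across all exposure-level records, and calls an
exposure **replicated** iff FDR-$p < 0.05$ in both stages *and* the two
coefficients share a sign. Directional consistency is a package default
(`require_direction = TRUE`): a sign-flipping "replication" is almost
surely two false positives, and the cost of demanding consistency under
the alternative is negligible.

# Multiple imputation

`impute_cohort()` implements chained random forests with predictive mean
matching. Each of $m$ copies (default $m = 5$) is initialized by draws
from the observed marginals; each sweep (at most 10) revisits every
incomplete column in order of increasing missingness, fits a
`ranger` forest (default 200 trees) of that column on all currently
completed baseline predictors plus the Nelson–Aalen cumulative-hazard
estimate at exit and the event indicator, and replaces each missing
numeric cell with the observed value of one of the $k = 5$ nearest donors
by predicted value. PMM keeps every imputation on the observed support;
categorical cells take the forest's majority class. Sweeps stop early
when the mean absolute change of imputed numeric cells falls below
$10^{-4}$. Imputation is performed separately within each region split so
the holdout never leaks into training imputations.

Downstream pooling follows Rubin's rules: $\bar Q$ the mean estimate, $W$
the mean within-imputation variance, $B$ the between-imputation variance,
$T = W + (1 + 1/m)B$, with a normal reference for $p$-values — at the
cohort sizes this pipeline targets the Barnard–Rubin small-sample
degrees-of-freedom correction changes nothing at the reported precision,
so it is omitted (a deliberate simplification, noted here). $R^2$,
correlation and C-index quantities pool on the Fisher-$z$ scale:
$r \mapsto \tanh(\mathrm{mean}(\mathrm{atanh}\, r))$, with $r = \sqrt{R^2}$
and $r = 2C - 1$ mapping those statistics into $(-1, 1)$ first.

With complete data every stage accepts $m = 1$ and pooling degenerates to
the single fit; the between-imputation term exists only for $m \ge 2$.

# Robustness filters

**Poor-health interaction rule.** Each replicated exposure's screening
model is augmented with the baseline poor-health indicator and its
interaction with the exposure. Remove iff the direct effect is no longer
significant ($p \ge 0.05$) while the interaction is ($p < 0.05$): the
association lives entirely in the prevalently ill, the signature of
reverse causation. The early-death sensitivity re-screen (excluding
deaths in the first 4 years) is computed and exported as an advisory
comparison; removal decisions are driven by the interaction rule.

**PheWAS flag rule.** Each surviving exposure is regressed (as the
outcome) on every panel phenotype with age and sex adjustment — linear
models for continuous/ordinal exposure outcomes, logistic for binary and
per-level-vs-reference for nominal ones. The removal judgment is codified
as two thresholds: remove iff any phenotype tagged
`disease_frailty_disability` or `exposure` reaches $p < 10^{-10}$ with
$|\beta| \ge 0.5$ standardized units. One deliberate coding choice: *all*
phenotypes are standardized to SD units, not only continuous ones. A raw
0/1 phenotype's coefficient is a mean difference, roughly $1.6\times$ the
latent correlation at typical prevalences, so a single effect threshold is
only meaningful when every phenotype is on the same scale. Every removal
is also emitted to a human-review report, because the rule codifies what
is ultimately a judgment call.

**Proteomic concordance.** Within the proteomic subsample, the proteomic
age gap (protein-predicted age minus calendar age, in years) is regressed
on each exposure with covariates sex, recruitment age, centre, education
and ethnicity; BH-FDR is computed across the exposures actually tested at
this stage. Retain iff FDR-$p < 0.05$ *and* the age-gap slope shares the
sign of the mortality coefficient; otherwise the removal reason is
recorded as `not_associated` or `discordant`. The filters are
deliberately order-independent: each reads only the original cohort and
the replicated set, so their composition is a pure intersection and
re-running any filter on its own survivors is a no-op.

# Correlation clusters and within-cluster pruning

The heterogeneous correlation matrix uses Pearson correlation for
continuous–continuous pairs, polyserial for continuous–ordinal and
polychoric (tetrachoric for binary) otherwise, each a two-step maximum
likelihood estimate: thresholds fixed at normal quantiles of the marginal
frequencies, then a 1-D profile-likelihood maximization over the latent
correlation. The bivariate normal rectangle probabilities use a
Gauss–Legendre quadrature of the Drezner–Wesolowsky form with a series
branch for $|\rho| > 0.925$ (absolute accuracy ~$10^{-14}$ against an
independent implementation). Per-copy matrices pool entry-wise by
Fisher-$z$.

Exposures are clustered on their **correlation profiles** — each exposure
is its row of the pooled matrix — with Euclidean distance and Ward
linkage. Profiles make Euclidean distance well-defined on a correlation
input; clustering on raw $|r|$ is available as an option. The tree is cut
at every $k$ in 1..25, the within-cluster sum of squares is computed in
the row-vector space, and the automatic elbow takes the $k$ maximizing
the second difference of the WSS curve; a manual $k$ override reproduces
the visual-elbow workflow. Within each cluster, members are first pruned
for collinearity — iteratively removing the worst offender with
GVIF$^{1/(2\,\mathrm{df})} > 1.6$ (Fox–Monette determinant-ratio form) and
recomputing, worst-first rather than simultaneous, so one redundant
variable cannot evict an entire correlated group — then all survivors
enter a single multivariable stratified Cox model with covariates centre,
household income, education and ethnicity (skipping any covariate already
a member); cluster survivors are members with pooled $p < 0.05$.

# Variance decomposition

Four nested Cox models per outcome on the **time-on-study** scale with
standardized recruitment age and sex as fixed covariates (no birth-cohort
strata — collinear with age on this scale): M1 age + sex; M2 adds the
outcome's PRS as quintile dummies (training-frozen boundaries) plus
genotype batch and genetic principal components (default 4 in the
synthetic setting; configurable); M3 adds the outcome's exposome; M4 adds
both. For mortality, all disease PRS enter M2 jointly. Categorical
exposures with fewer than 10 outcome cases in any level are excluded from
that outcome's exposome. Proportional hazards are checked per model via
scaled Schoenfeld residuals (identity time transform, $\alpha = 0.05$);
violators are refit with 2-year episode splitting and
covariate-by-episode-start interactions — splitting alone leaves the
partial likelihood bit-identical, a property the tests assert at
$10^{-6}$.

Explained variation is the explained-randomness
$R^2 = 1 - \exp(-\mathrm{LR}/d)$ with $d$ the **event count** — the
events-normalized form; the denominator is exposed as config
(`denominator = "subjects"`) since the literature uses both. Importance is
the share of each category's Wald $\chi^2$
($\chi^2_g = \beta_g' V_{gg}^{-1} \beta_g$) in the total, with the PRS
category including the batch and PC covariates; the shares sum to 1.
Holdout validation freezes the training coefficients (and exposure
standardization statistics and PRS quintile boundaries), computes the
linear predictor on the holdout region, and fits a one-covariate Cox of
the holdout outcome on that predictor — an unconstrained refit, so its
slope doubles as a calibration check (≈ 1 under exchangeability).

# The synthetic cohort generator

The generator is the package's test bed and defines the study conditions
for every property test. Defaults: $n = 20{,}000$ participants (the
pipeline also runs at $10\times$ this; all tests use desk scale), age
$\sim N(57, 8.1^2)$ truncated to 40–70, 54% female, an 11.3% holdout
region, administrative censoring uniform on 11–15 years, and a Gompertz
baseline hazard $h(a) = A e^{0.09 a}$ with $A$ calibrated by bisection so
the expected death fraction over the realized age/censoring/linear-
predictor mix is 7.3%. Event ages are drawn by inverse transform on the
conditional survivor function given survival to recruitment age, so left
truncation is exact by construction (the tests push the draws back
through the cumulative hazard and get uniforms).

The exposome is a blocked Gaussian copula: 42 exposures in 7 blocks with
within-block latent correlation 0.45 and independent blocks, thresholded
to a declared type mix (45% continuous, 25% ordinal with equal-probability
cuts, 20% binary at prevalence 0.3, 10% nominal via argmax over latent
dimensions with a dominant reference level). Planted structure:

* 8 **causal** exposures with per-SD mortality log-HRs
  ±{0.405, 0.30, 0.25, 0.20, 0.15} and proteomic age-gap slopes
  $\gamma = 2.5\beta$ years/SD (gap residual SD 4 y, carried by a 10.4%
  training subsample);
* 1 **confounded** decoy loading 0.8 on the latent income scale, which
  itself carries log-HR −0.35/SD — marginally mortality-associated, and
  flagged by the PheWAS rule through its income association;
* 2 **reverse-causation** decoys with no direct effect: each loads on the
  poor-health indicator (logit slope 1.0) and interacts with it in the
  hazard ($\theta = 0.8$), and the entire poor-health hazard block acts
  only during the first 4 years of follow-up — prevalent illness kills
  early, which is exactly what the early-death and interaction analyses
  are built to catch;
* 2 **mortality-only** decoys ($\beta = \pm 0.3$, $\gamma = 0$) and 1
  **sign-discordant** decoy ($\beta = +0.2$, $\gamma = -0.5$) for the
  proteomic concordance rule.

Decoys live on independent latents rather than inside blocks; otherwise
their planted failure modes would be contaminated by correlation with
causal block-mates and no filter could be scored cleanly. Correlated
**null** block-mates of causal exposures do replicate in the screen — by
construction, as in real exposome data — and are removed by the
within-cluster multivariable models, not by the filters.

Ancillary columns: per-disease Gompertz incidence (defaults 5 diseases at
5%/5%/4%/3%/0.2% incidence) with PRS effects {0.10, **0.50**, 0.20, 0.15,
0} per SD — disease 1 is exposome-driven, disease 2 PRS-driven, disease 5
a rare null analogue; standard-normal PRS, 4 Gaussian PC stand-ins and a
batch indicator; lognormal biomarkers with age slopes and planted
exposure effects; three binary risk factors. Missingness, when
configured, is MAR with logit-linear dependence on age, sex and income
band, the intercept calibrated per column to the requested rate; rates at
or above 0.8 are rejected, mirroring the exposure inclusion rule.

**What the generator does not emulate:** real measurement error and
nonlinear dose-response; informative censoring; time-varying exposures;
genuine genotypes or proteomic expression (the PRS and age gap are
emitted directly); joint missingness mechanisms beyond
MAR-on-observables (the real joint mechanism is unknown; MAR is a
stand-in, not a claim). Passing tests therefore demonstrate that the
pipeline recovers planted structure under its own assumptions, not that
those assumptions hold in any particular cohort.

# Problem sizes, determinism and numerical choices

One master seed fans out deterministically into per-stage child seeds;
two runs with equal config and seed produce byte-identical exports
(numeric TSV columns are fixed at 6 significant digits for stable diffs).

The test and acceptance workloads state their own scales, chosen to make
each property sharp at desk size: single-fit effect recovery at
$n = 10^5$ (±0.03 on a planted log-HR of 0.405); CI coverage over 500
replicates at $n = 2{,}000$; screen calibration under a global null of
200 exposures over 20 seeds at $n = 6{,}000$ (the null false-replication
rate does not depend on $n$); decoy/filter recovery over 20 seeds at the
default $n = 20{,}000$; cluster recovery over 20 seeds at $n = 4{,}000$;
the decomposition contrast at $n = 50{,}000$, where the ~25 null PRS
parameters cost well under 1 R² percentage point against ~3,200 events
(at much smaller event counts the chance LR of that many parameters
alone approaches 1 pp and the M4−M3 contrast stops being informative
about the science). Filter-recovery and decomposition runs use
complete-data cohorts ($m = 1$): decoy removal and R² partitions do not
depend on the missingness mechanism, and the imputation engine is
validated separately against the generator's held-back truth
(Kolmogorov–Smirnov distance of imputed vs masked-true values, plus
bitwise invariance of observed cells). Holdout exchangeability is
asserted on the mean absolute train-holdout C-index difference across
seeds (< 0.02): individual holdout C estimates at a few hundred events
carry sampling noise of the same order as the band itself.

Other numerics: Cox convergence at relative log-likelihood change
$10^{-10}$ (≤ 50 iterations) with monotone-likelihood divergence flagged
at $|\beta| > 20$, never silent; rank-deficient designs are an error
naming the aliased columns; polychoric/polyserial maximization by 1-D
golden-section on $(-0.999, 0.999)$ with cell probabilities floored at
$10^{-12}$; the WSS elbow needs at least three scanned $k$; Efron ties by
default with Breslow as the config alternative (no exact option).

# Known limitations

* Only linear (per-SD or per-level) exposure effects are screened; no
  polynomial contrasts.
* The PheWAS flag rule is a codification of a judgment call; its two
  thresholds are config, and a review report accompanies every removal.
* Rubin pooling uses the normal reference; small-$m$, small-$n$ settings
  would want the Barnard–Rubin correction.
* The elbow selector maximizes the second WSS difference; clean block
  structure gives a decisive elbow, but weak or nested structure may need
  the manual override, which is why it exists.
* `run_pipeline()` resumability is in-memory (pass the previous run
  object), not an on-disk stage store.
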