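# admixSMR

Subcontinental ancestry components and disease-specific mortality: an R
package implementing a two-stage aggregate-data (ecological) analysis that
estimates, per disease category, the standardized mortality ratio (SMR)
associated with a 1 percentage-point increase in a genetic ancestry
component — together with the genotype processing, supervised ancestry
estimation, sensitivity procedures and individual-level survival validation
that surround it, and a synthetic-data generator with known ground truth
that makes the whole pipeline testable end to end without any external data.

## Who this is for

Statistical geneticists and genetic epidemiologists studying admixed
populations in which a *subcontinental* distinction matters: two closely
related ancestral components (here, two Native American-like components at
pairwise Fst ≈ 0.038 on a strong regional gradient) can carry
opposite-signed disease associations that cancel when the components are
pooled, and a pooled continental surrogate reference panel systematically
underestimates the ancestry of individuals dominated by the locally drifted
component. The package reproduces, under controlled synthetic conditions,
both phenomena and the machinery used to detect them.

## The model

**Supervised ancestry.** For an individual with dosages `g_m ∈ {0,1,2}` at
M biallelic SNPs and fixed reference alternate-allele frequencies `f_km`
for K ancestral populations, the admixture proportions `q` maximize

    ℓ(q) = Σ_m [ g_m log(Σ_k q_k f_km) + (2 − g_m) log(Σ_k q_k (1 − f_km)) ]

over the K-simplex (EM, SQUAREM-accelerated for cohorts; an exhaustive
simplex-grid oracle checks the optimizer in the tests).

**Two-stage association.** Stage 1 regresses each individual ancestry
proportion X on categorical covariates and region, `E[X|Z] = Z'd` (OLS with
stepwise forward selection at level 0.1), yielding expected regional
proportions and their standard errors. Stage 2 models yearly
disease-specific age-standardized mortality rates Y per region as

    Y ~ Poisson(μ),   log(μ) = β · E[X|Z] + Z̃α + ε

with `E[X|Z]` in percentage points, a log person-years offset and
cluster-robust (by region) errors, so `exp(β)` is the SMR per 1% ancestry.
Categories with fewer than 100 national deaths are dropped and associations
highlighted at `p < 0.05 / n_categories`.

**Sensitivity.** Leave-one-out influence on regional ancestry means with a
2/n flag; resampling of regional expectations from `Normal(E, scale·SE)`
with the SMR summarized by median and 2.5th/97.5th percentiles;
ancestry-informative-marker selection by non-overlap of 80% Wilson MAF
confidence intervals; adjustment for extra regional covariates. A Cox
proportional-hazards stage validates an association at the individual level
(hazard ratio per 1% ancestry, Breslow ties).

## Worked example

```r
library(admixSMR)

cfg <- pipeline_config(seed = 101, resample_S = 2)
bundle <- run_pipeline(cfg)

bundle$qc_report
#> <qc_report>
#>   variants in:           8000
#>   removed non-autosomal: 0
#>   removed missingness:   0
#>   removed MAF:           331
#>   removed LD:            0
#>   variants out:          7669

subset(bundle$report, icd == "C23" & component == "Mapuche")
#>   icd                       description deaths component       beta          se
#> 2 C23 Malignant neoplasm of gallbladder   9779   Mapuche 0.03587366 0.001847596
#>        smr ci_lower ci_upper            p highlight
#> 2 1.036525 1.032426  1.04064 1.605932e-11      TRUE
```

The generative truth for this category is an SMR of 1.037 per 1%
Mapuche-like ancestry: each 1-point increase in the expected regional
Mapuche-like proportion multiplies gallbladder-cancer-like standardized
mortality by the fitted `smr`, here recovered as ≈ 1.0365 with a 95%
cluster-robust interval covering the truth, flagged significant at the
Bonferroni-style threshold. `excess_projection(1.037, 24)` expresses the
same effect as the 88.8% excess implied by a 24-point regional contrast.

The masking experiment contrasts pooled and split analyses:

```r
res <- experiment_masking(seed = 3, replicates = 50)
res$masking_summary
#> $split_signs_correct: 1        # Mapuche-like SMR > 1, Aymara-like < 1
#> $split_cis_exclude_1: 1
#> $pooled_ci_covers_1:  1        # pooled Native sum: association masked
#> $pooled_attenuated:   1
#> $true_smr:            1.03
res$estimation$slope
#> [1] 0.5651863                  # pooled-surrogate vs split-sum: < 1
```

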