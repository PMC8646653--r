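# pathprs

**Pathway-stratified polygenic risk scores and cross-trait genetic
association analysis**

`pathprs` asks, end to end, whether an ordinal, strongly age-dependent trait
— male androgenetic alopecia (AGA), self-reported on the four-level
pictogram scale (1 = no balding … 4 = complete baldness of the scalp) — is
associated with a binary disease outcome, hospitalization with COVID-19,
and at which level any association lives:

1. **Epidemiology.** Two-stage age correction: OLS of the numeric pattern on
   age at assessment, then maximum-likelihood logistic regression of
   hospitalization on the balding residuals and age at event
   (β = log-odds per residual unit, Wald tests). Includes the 52–59
   age-window subset and the severe-balding prevalence comparison by age
   group under both severity definitions (patterns 3+4, pattern 4 only).
2. **Genome-wide genetics.** Cross-trait LD score regression:
   χ²ⱼ = 1 + N h² ℓⱼ/M per trait, z₁ⱼz₂ⱼ regressed on √(N₁N₂) ℓⱼ/M for the
   genetic covariance, r_g = gencov/√(h₁²h₂²) with a leave-one-block-out
   jackknife SE.
3. **Pathway genetics.** Polygenic risk scores in sum-calculation mode
   (Σⱼ βⱼ·dosageᵢⱼ) at p < 5×10⁻⁸ and p < 5×10⁻⁵ with greedy LD clumping;
   pathway-restricted scores (pPRS) built by positional SNP-to-gene mapping
   (distance strictly < 10 kb) against three gene-set libraries;
   age-corrected logistic association per sex, threshold and library, with
   Benjamini–Hochberg FDR within each such iteration.

Individual-level biobank data are restricted, so the package includes a
first-class synthetic-cohort generator (LD-blocked threshold-Gaussian
genotypes, liability-threshold ordinal patterns, logistic outcomes with an
optional shared genetic component confined to one planted pathway, and
summary statistics drawn from the bivariate LD score model) with fully
known ground truth. Standard formats — VCF, summary-statistic TSV, GMT,
BED-like annotation — are read and written, so the same pipeline runs on
real GWAS resources.

## Worked example

Simulate a cohort of 8 000 test-positive individuals in which
hospitalization risk rises with age (log-OR 0.1/year) and carries a shared
genetic component of 0.3 log-odds per SD confined to one 20-gene pathway,
then run the whole analysis:

```r
library(pathprs)

cfg <- sim_config(n_individuals = 8000,
                  planted_pathway_id = "wnt_like_signalling",
                  shared_effect_size = 0.3, seed = 2026)
res <- run_cohort_analysis(cfg)

print(res$summary)
#> Cohort: 8000 individuals (4033 men, 3967 women)
#>   hospitalized: 369 men (ratio 1:9.9), 344 women (ratio 1:10.5)
#>   AGA patterns 1-4 among 4033 men: 30% / 23% / 28% / 19%
#>   median age at event (men 68, women 67; hospitalized 72 / 71)

print(res$epi)
#> Age-corrected AGA ~ severe COVID-19 regression (full cohort)
#>   beta = 0.134, se = 0.051, p = 0.0085 (n = 4033, 369 cases)
```

The control:case ratios, pattern distribution and age gradient mirror the
structure of a real test-positive cohort; because the planted pathway makes
part of the balding genetics also raise hospitalization risk, even the
age-corrected epidemiological regression picks up a genuine positive signal
here. The pathway scan localizes it:

```r
top <- res$pprs[res$pprs$status == "ok", ]
head(top[order(top$p_fdr), c("library", "pathway", "sex", "threshold",
                             "n_variants", "beta", "p", "p_fdr")], 4)
#>         library             pathway    sex threshold n_variants  beta        p    p_fdr
#>  kegg_like_2019 wnt_like_signalling female     5e-05         11 0.323 1.79e-08 6.28e-07
#>  kegg_like_2019 wnt_like_signalling female     5e-08          7 0.296 3.12e-07 7.17e-06
#>  kegg_like_2019 wnt_like_signalling   male     5e-05         11 0.255 5.30e-06 1.86e-04
#>  kegg_like_2019 wnt_like_signalling   male     5e-08          7 0.242 1.72e-05 3.95e-04
```

The planted pathway tops every iteration it appears in; its `beta` is the
log-odds of hospitalization per SD of the pathway score, recovering the
generating value 0.3. With `shared_effect_size = 0` the same pipeline is
null-calibrated (5% rejections at α = 0.05, no FDR discoveries beyond the
nominal level) — that is what the acceptance experiments below verify.

`run_pipeline(cfg, out_dir)` runs the same stages plus the GWAS of both
traits and LD score regression, writing every intermediate (VCF, dosage and
phenotype TSVs, GMT libraries, summary statistics, LD scores, score and
association tables) and a JSON manifest with per-file checksums.

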