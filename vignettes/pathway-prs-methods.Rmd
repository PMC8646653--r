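---
title: "Methods: pathway-stratified polygenic scores and cross-trait association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-stratified polygenic scores and cross-trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Male androgenetic alopecia (AGA) was proposed as a clinical marker of severe
COVID-19 after reports of high prevalence of advanced balding among
hospitalized men. Both traits, however, depend strongly on age, and the
original comparisons mixed cohorts scored with different balding criteria.
`pathprs` implements the analysis strategy that interrogates this putative
link at three levels:

1. **Epidemiology** — an age-corrected regression of hospitalization on the
   ordinal balding pattern within one cohort of SARS-CoV-2-positive men.
2. **Genome-wide genetics** — cross-trait LD score regression on GWAS
   summary statistics, estimating the genetic correlation $r_g$.
3. **Pathway-level genetics** — polygenic risk scores restricted to the
   variants near genes of individual pathways (pPRS), tested per sex,
   p-value threshold and gene-set library with per-iteration FDR control.

Individual-level biobank data are not redistributable, so the package ships
a synthetic-cohort generator whose ground truth is fully known. Every stage
of the pipeline is exercised and validated against that ground truth; the
file formats (VCF, summary-statistic TSV, GMT, BED) are the standard ones,
so the same code paths run on real resources.

# The synthetic cohort

## Genotypes

Genotypes follow a threshold-Gaussian haplotype model. Variant $j$ receives
an allele frequency $f_j \sim U(\text{maf\_range})$. Within an LD block of
`ld_block_size` consecutive variants, the per-haplotype latent Gaussians
share equicorrelation $\rho$ (`within_block_corr`), implemented as
$\sqrt{\rho}\,u_b + \sqrt{1-\rho}\,e_{j}$ with a common block factor $u_b$.
A haplotype carries the coded allele when its latent variable exceeds
$\Phi^{-1}(1-f_j)$, and the dosage is the sum of two independent haplotypes.
Marginally every variant is in Hardy–Weinberg equilibrium with mean $2f_j$
and variance $2f_j(1-f_j)$; within blocks the dosage correlation is a
monotone, tunable function of $\rho$. Blocks are independent and never span
chromosomes. This reproduces the two features the downstream methods
actually consume — allele-frequency spectra and local LD — while omitting
recombination-map realism, population structure and relatedness, which are
out of scope. Consequently, passing tests demonstrate correctness of the
estimators under their own modelling assumptions, not robustness to
stratification or cryptic relatedness in real biobank data.

The sampler is written in C++ (Rcpp) because it is the innermost loop of
every replication experiment; it draws from R's RNG, so all output is
reproducible from the configuration seed. Per-stage sub-seeds are derived
deterministically from the global seed, making every generated object
bit-identical under an identical configuration.

## Gene annotation and libraries

Genes are tiled deterministically: fixed length (default 10 kb), fixed
intergenic gap (default 30 kb), 1-based inclusive coordinates. With the
10 kb mapping window this leaves ~25% of positions unmapped, so the
distinction between mapped and unmapped variants is exercised. Three
gene-set libraries are generated (mimicking the use of KEGG-, WikiPathways-
and Panther-style collections), each holding `n_pathways_per_library`
random pathways of `genes_per_pathway` genes; pathways overlap freely, as
real curated libraries do. A designated *planted* pathway can be placed in
the first library.

## Phenotypes

The male balding pattern (1 = no balding … 4 = complete baldness; females
carry no pattern, mirroring self-report cohorts where balding information
is only available for men) comes from a liability-threshold model:

$$L_i = g_i + \beta_{\text{age}}(a_i - \bar a) + \varepsilon_i,
  \qquad g_i \sim \text{var } h^2,\ \varepsilon_i \sim N(0, 1-h^2),$$

cut at three fixed thresholds chosen on the theoretical liability scale so
the marginal pattern distribution approximates 31/23/27/19% — the
self-reported distribution in the motivating cohort, normalized to sum to
one. The genetic score $g_i$ sums `aga_n_causal` random causal variants
(default 120 of 2000). A deliberately **sparse** architecture is used: at
desk-scale sample sizes an infinitesimal model would leave no variant
passing the $5\times10^{-8}$/$5\times10^{-5}$ selection thresholds, whereas
real AGA GWAS are dominated by a set of strong loci. The default
$h^2 = 0.6$ matches the high heritability of balding.

Hospitalization is Bernoulli with

$$\operatorname{logit} P(\text{hosp}_i) = c +
  \beta_{\text{cov,age}} (t_i - \bar t) + \gamma\, s_i,$$

where $t_i$ is the age at the hospitalization/test event (assessment age
plus 2–13 years, so the two regression stages use genuinely different
ages), $\gamma$ is `shared_effect_size` (log-odds per SD), and $s_i$ is the
standardized score over exactly the variants mapped within <10 kb of
planted-pathway genes, weighted by their balding effect sizes. Outside the
planted pathway the shared effect is identically zero — the ground truth
the recovery tests rely on. The intercept $c$ is solved numerically so the
marginal hospitalization rate equals `covid_base_rate` (default 0.09,
matching the case fraction of the motivating cohort). Every simulated
individual is SARS-CoV-2-positive; hospitalized individuals are the cases.

Defaults: assessment ages $U(50, 70)$ years, event ages therefore spanning
roughly 52–83; `aga_age_slope` = 0.03 liability units/year;
`covid_age_log_or` = 0.1 per year — strong age dependence of both traits,
which is the crux of the confounding argument.

## Model-consistent summary statistics

For testing the LD score regression estimator directly,
`simulate_model_sumstats()` draws z-score pairs per variant from the
bivariate generating model,
$\mathrm{Var}(z_{ij}) = 1 + N_i h_i^2 \ell_j / M$ and
$\mathrm{Cov}(z_{1j}, z_{2j}) = \sqrt{N_1 N_2}\, r_g \sqrt{h_1^2 h_2^2}\,
\ell_j / M$, with the sample-overlap term fixed at zero (the analysis this
emulates used a COVID GWAS excluding the biobank cohort, so overlap is
minimal; the estimator nevertheless keeps a free intercept).

# The estimators

## Two-stage age-corrected regression

Stage one regresses the numeric pattern (1–4) on age at assessment by OLS,
among males with a pattern; the pattern is treated as numeric, keeping one
residual per person. Stage two is a maximum-likelihood logistic regression
of hospitalization on (intercept, residual, age at event), with Wald tests
on the residual coefficient and observed-information standard errors — the
default of mainstream GLM implementations. The same machinery serves the
52–59 age-window subset analysis. Because stage two includes the residual
directly, the "two-stage" estimate *is* the residual coefficient of a
single logistic fit on (residual, event age) — there is no separate
plug-in approximation to test.

The prevalence comparison (`prevalence_by_age_group()`) uses seven default
age bins — 52–54, 55–59, then 5-year bins to 79, and 80–83. The boundary
list is configurable because only the first two bins are pinned down by the
analysis that motivated them; descriptions of the binning elsewhere vary
between six and seven groups, so the bin table is an argument, not a
constant. Both severity definitions (patterns 3+4; pattern 4 only) are
supported, and the pattern-4-only prevalence can never exceed the 3+4
prevalence in any bin, which is asserted in the tests.

## LD score regression

LD scores are $\ell_j = \sum_k r^2_{jk}$ over variants within a 1 Mb window
on the same chromosome, self-term included, with an optional
$r^2 - (1-r^2)/(n-2)$ small-sample adjustment. Heritability is the slope of
the weighted regression $\chi^2_j = z_j^2$ on $N \ell_j / M$ with free
intercept; genetic covariance is the slope of $z_{1j} z_{2j}$ on
$\sqrt{N_1 N_2}\,\ell_j / M$; and $r_g = \widehat{\text{gencov}} /
\sqrt{\hat h_1^2 \hat h_2^2}$. Weights default to $1/\max(\ell_j, 1)$ — the
first-order heteroskedasticity correction — with an unweighted option; the
full iterative weighting scheme of the reference implementation is
intentionally out of scope, and the choice is isolated in one function.
Standard errors come from a leave-one-block-out jackknife over 50
contiguous variant blocks (50 rather than the reference tool's 200 because
desk-scale panels have a few thousand variants, and jackknife blocks must
stay large relative to the LD window). Intercepts are always free; there is
no constrained-intercept mode since sample overlap is generally unknown.
When either heritability estimate is non-positive, $r_g$ is reported as
undefined with both estimates and a reason string — never a silent `NaN`.

## Polygenic scores

Scores are plain weighted dosage sums ("sum-calculation mode") over
variants passing a strict `p < threshold` filter (defaults
$5\times10^{-8}$ and $5\times10^{-5}$), optionally LD-clumped first.
Clumping is greedy: lowest p first, removing neighbours within 250 kb at
$r^2 \ge 0.1$ (the defaults of the standard scoring tool, since the
original analysis does not state its clumping parameters; both are
configurable and clumping can be disabled). Ties in p break by
(chromosome, position), so the procedure is deterministic. Scores are
z-scored within each sex stratum before the logistic association
(hospitalization ~ score + event age), so effects are log-odds per SD; this
also makes the association invariant to any linear rescaling of the raw
score. Male X-chromosome dosages default to the hemizygous 0/2 coding with
a 0/1 option.

## Pathway scores and FDR

Variants map to a gene when their distance to the gene interval is
*strictly* less than 10 kb (distance 0 inside the gene); a variant may map
to several genes, and enters a pathway's variant set once regardless of how
many member genes it maps to. A pathway's score restricts the genome-wide
thresholded, clumped variant set to the pathway's mapped variants —
clumping is done once genome-wide and then intersected (clump-then-restrict
matches computing pathway scores "as previously described" from the same
selected variants; a within-pathway clumping flag exists for the
alternative reading). One *iteration* is a (sex, threshold, library) cell;
Benjamini–Hochberg adjustment (the standard reading of "false discovery
rate") is applied to exactly the pathways tested within an iteration.
Pathways with fewer than `min_variants` (default 1) variants are excluded
and logged; failed regressions are flagged and leave the iteration's FDR
family. A `library`-pooled FDR scope is available because the original
phrasing of "per iteration" is ambiguous about granularity.

# Numerical choices and degenerate inputs

* Logistic fits in the pathway scan use a Newton–Raphson solver with a
  divergence guard, falling back to the reference IRLS implementation and
  raising an explicit separation error if both fail. The fast path agrees
  with `stats::glm` to $10^{-6}$ (asserted in tests).
* Monomorphic variants: flagged, correlations defined as zero in LD scores,
  missing effect estimates in the GWAS — never fatal.
* Strand-ambiguous palindromic variants (A/T, C/G) are removed outright in
  harmonization; no frequency-based rescue, the conservative standard.
  Variant matching is by id with a chromosome+position fallback.
* Coordinates are 1-based inclusive (VCF convention) everywhere inside the
  package; BED export converts at the boundary and says so in its header.
* Empty variant selections produce all-zero scores with a warning; constant
  scores produce an `NA` association with a warning rather than an error,
  so a scan never dies on one degenerate pathway.

# Problem sizes used in the validation experiments

The replication experiments shipped with the package use: 200 cohorts of
n = 5000 with 2000 variants and 3×50 pathways for the null-calibration
study; 20 cohorts of n = 10 000 for planted-pathway recovery
(shared effect 0.3 log-odds/SD confined to one 20-gene pathway); 20
generator seeds at M = 2000, N = 20 000, $h^2 = 0.3$ for LD score
regression recovery at $r_g \in \{0, 0.5\}$; and 50 cohorts of n = 20 000
(50 variants, no genetic effects) for the age-confounding demonstration.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances (e.g. ±1.5 percentage points on a 5% rejection rate
over 200 replicates) while a full validation run completes on a single CPU
in well under half an hour.

# Known limitations

* The genotype model has block-diagonal LD with equicorrelated latents; it
  cannot produce long-range LD, allele-frequency-dependent LD, or
  structure-driven confounding of the polygenic scores.
* The heritability estimator uses single-component LD score regression;
  partitioned/stratified variants are out of scope.
* The ordinal pattern is analysed as numeric 1–4 in the first regression
  stage, an ordinal-as-linear reading; no proportional-odds alternative is
  provided.
* The pipeline's GWAS assumes unrelated individuals (no mixed models) and
  performs no imputation, phasing, or ancestry inference.
* X-chromosome support is limited to the dosage-coding convention in
  scoring; the generator itself produces autosomes only.
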