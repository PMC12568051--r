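---
title: "GWAS-prior-weighted genomic prediction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWAS-prior-weighted genomic prediction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gablup)
```

This vignette is the package's own account of the statistics it implements:
the repeated-record animal model, the additive and dominance genomic
relationship matrices, the GWAS-prior weighting (GBLUP–GA), the REML
machinery, and the cross-validation design — together with the judgement
calls made where several defensible choices existed.

## The model

Economic traits in fibre-producing goats and sheep are recorded repeatedly:
an animal is shorn or combed every year, so each individual contributes
several records taken under different flock, age and year conditions. The
package fits

$$y = Xb + Zu + Wp + Vd + e$$

at the record level, where $b$ holds the fixed factors (flock, age, sex,
measurement year, all treated as categorical), $u \sim N(0, G\sigma_a^2)$
are additive genomic values, $p \sim N(0, I\sigma_p^2)$ are
permanent-environment effects (individual-constant, non-genetic),
$d \sim N(0, D\sigma_d^2)$ are dominance values, and
$e \sim N(0, I\sigma_e^2)$ are record-level residuals. The three random
terms share one records-by-individuals incidence matrix (each record belongs
to exactly one individual); the package exploits this: with
$K = \sigma_a^2 G + \sigma_p^2 I + \sigma_d^2 D$ the phenotypic covariance
is $V = Z K Z' + \sigma_e^2 I$ and every REML iteration reduces to
individuals-by-individuals linear algebra via the Woodbury identity,
regardless of the record count.

Derived genetic parameters are the additive heritability
$h_a^2 = \sigma_a^2/\sigma_T^2$, the dominance heritability
$h_d^2 = \sigma_d^2/\sigma_T^2$, and the repeatability
$r = (\sigma_a^2+\sigma_d^2+\sigma_p^2)/\sigma_T^2$ with
$\sigma_T^2$ the sum of all four components.

## Relationship matrices

The additive matrix is VanRaden's: allele counts $M \in \{0,1,2\}$ (copies
of the counted allele, fixed as PLINK allele 1 so the coding is
reproducible) are centered columnwise by $2p_i$ and
$G = ZZ'/2\sum_i p_i(1-p_i)$. Allele frequencies are always the observed
sample frequencies of the full genotyped sample, recomputed after QC and
*not* recomputed for SNP subsets — so prior-set and residual-set matrices
decompose exactly: $Z_{\text{all}}Z_{\text{all}}' =
Z_1 Z_1' + Z_2 Z_2'$ before scaling.

The dominance matrix uses the heterozygosity indicator $h \in \{0,1\}$
centered by its Hardy–Weinberg expectation $2p_jq_j$, scaled by
$4\sum_j p_j^2 q_j^2$. This is a deliberately *hybrid* coding: the
$\{0,1\}$ indicator with $2pq$ centering belongs to the "genotypic"
dominance parameterisation (whose natural denominator is
$\sum 2p_jq_j(1-2p_jq_j)$), while $4\sum p^2q^2$ is the denominator of the
dominance-*deviation* parameterisation. The combination is what is
conventionally written in the goat/sheep dominance-GBLUP literature this
package follows, so it is the default; `build_dominance_grm(center =
"observed")` gives the pure indicator alternative. One visible consequence:
the mean diagonal of $D$ is not 1 — under Hardy–Weinberg it is
$\sum 2pq(1-2pq) / 4\sum p^2q^2$, about 1.46 for frequencies uniform on
$[0.05, 0.5]$ — and the tests check exactly that expectation rather than a
nominal 1. Dominance variances estimated on this scale are therefore tied to
this scaling, as are their heritabilities.

Matrices built from small SNP subsets (a top-5% set can easily hold fewer
SNPs than there are individuals) are rank-deficient, so anything destined
for inversion passes through `regularize()`: a ridge of
$10^{-6} \times \text{mean diagonal}$ by default, which shifts every
eigenvalue by exactly that amount and is recorded on the object.

## The GWAS prior and the weight tau

SNPs are ranked by association p-value (smallest first, ties broken by map
position then id so the split is deterministic) and the top fraction
$f \in \{0.05, 0.10, 0.15, 0.20\}$ becomes the prior set, with
$\lfloor f \cdot n \rfloor$ SNPs. The floor rule is pinned because no single
rounding rule reproduces every published panel count; the two counts the
acceptance arithmetic uses (top 5% and top 15% of 50,728) are invariant to
that choice.

Two *separate* REML fits — one with only the prior-set matrices
$(G_1, D_1)$, one with only the residual-set matrices $(G_2, D_2)$, each
with the full fixed-effect and permanent-environment structure — yield the
genetic variances entering

$$\tau = \frac{\sigma^2_{Ga1} + \sigma^2_{Gd1}}
             {\sigma^2_{Ga1} + \sigma^2_{Gd1} + \sigma^2_{Ga2} + \sigma^2_{Gd2}},$$

and the trait-specific matrices are $G_t = \tau G_1 + (1-\tau)G_2$ and
$D_t = \tau D_1 + (1-\tau)D_2$. Separate fits (rather than one joint fit
with both matrix pairs) are the default because the published component
tables this design mirrors report distinct permanent-environment and
residual estimates per matrix set, which only separate fits produce. The
final model refits all variance components with $(G_t, D_t)$ rather than
reusing either partition fit. Components pinned at the variance floor enter
the $\tau$ ratio at the floor value, which reproduces the tiny
$10^{-3}$-scale entries seen in such tables; if every genetic variance is
exactly zero $\tau$ is undefined and set to $0.5$ with a warning. Dominance
matrices are partitioned and recombined with the same $\tau$ as the
additive ones — the conservative reading of a table layout that reports
dominance variances per partition. Cashmere-length-like traits are fitted
without any dominance term (`model_spec(include_dominance = FALSE)`).

The built-in scan (`run_ad_gwas`) exists so synthetic end-to-end runs are
self-contained: records are adjusted for the fixed factors by least squares,
averaged per individual, and each SNP is tested with an additive covariate
plus a heterozygosity indicator against the intercept-only model by an
F-test. It deliberately ignores relatedness; the pipeline accepts external
p-values wherever a table is expected, which is the intended use when a
proper mixed-model GWAS is available.

## REML: algorithm and numerical choices

Variance components are estimated by average-information REML with EM
fallback:

* **Updates.** Newton steps using the analytic score and the
  average-information matrix (both validated in the tests against finite
  differences and a dense-matrix likelihood oracle), with step halving; when
  an AI step fails or cannot increase the restricted likelihood, an EM-style
  step $\Delta\sigma_i^2 = 2\sigma_i^4\,s_i/q_i$ (with $s_i$ the score) is
  tried under the same acceptance rule. Every accepted step increases the
  restricted log-likelihood, so the trajectory is monotone.
* **Convergence.** Relative log-likelihood change below $10^{-8}$ (the
  package default) within 200 iterations; cross-validation runs use
  $10^{-6}$/$10^{-7}$ and fewer iterations, which changes accuracies only in
  the fourth decimal while cutting run time substantially.
* **Boundaries.** Components are floored at $10^{-8} \times$ the sample
  phenotypic variance. A component at the floor with a negative score is
  pinned and leaves the update set (it may re-enter if its score turns
  positive). Near-zero published estimates (e.g. permanent-environment
  variances of order $10^{-7}$) are exactly this boundary behaviour.
* **Identifiability.** With essentially unrelated individuals the dominance
  matrix is close to a scaled identity, so $\sigma_p^2$ and $\sigma_d^2$ are
  only weakly separated by the off-diagonal structure; in simulations with a
  true $\sigma_p^2 = 0$ the estimate collapses to a negligible share of the
  phenotypic variance but is not always exactly pinned. This is a property
  of the design (few records, near-diagonal $D$), not of the optimiser.
* **Starting values** are fixed fractions (0.3/0.1/0.1/0.5) of the
  fixed-effect-adjusted phenotypic variance, overridable; cross-validation
  warm-starts each fold from the previous fold's estimates.

Predictions solve Henderson's mixed-model equations exactly as written, with
$\alpha_1 = \sigma_e^2/\sigma_a^2$, $\alpha_2 = \sigma_e^2/\sigma_p^2$,
$\alpha_3 = \sigma_e^2/\sigma_d^2$; terms excluded by the model spec drop
out of the block system. Individuals without records still receive additive
solutions — that is how validation animals are predicted. The solver is
tested to $10^{-8}$ against the direct conditional-expectation (GLS/BLUP)
oracle on random toys. One classical-looking invariance deliberately does
*not* hold and is tested in its correct form: duplicating every record does
not leave fixed-effect estimates unchanged in a mixed model (it changes the
data's weight against $\alpha_1 G^{-1}$); the exact identity is that
duplication is equivalent to halving $\sigma_e^2$.

## Cross-validation design

Folds are drawn over individuals, never records, so repeated records of one
animal never straddle training and validation. Per fold, validation
phenotypes are masked and the entire chain — scan (when p-values are not
supplied), partition, two partition fits, $\tau$, $G_t/D_t$, refit, MME —
runs on training records only; the tests verify that perturbing validation
phenotypes leaves $\tau$ and the training heritability bit-identical. When
external p-values are supplied they are used as-is for every fold and a
message flags the potential leakage, since prior GWAS results computed on
the full population are the realistic use case.

The validation response is the fixed-effect-adjusted phenotype: each record
minus its fitted fixed part (training estimates), averaged per individual;
records with factor levels unseen in training are dropped with a warning.
Accuracy is reported in two conventions, because the covariance-based
formula that circulates in the applied literature is scale-dependent and
ambiguous about its denominator: the default `cor_over_h` is
$\mathrm{cor}(a, \hat u)/\sqrt{h^2}$ (predictive ability rescaled to the
accuracy scale; can exceed 1 when the fold underestimates $h^2$), and
`literal_cov_over_h2` is $\mathrm{cov}(a, \hat u)/h^2$ exactly as printed in
that literature. Both use the additive heritability of the same fold's
training refit. Scenario effects are judged by a one-way linear model of
fold accuracy on scenario with its ANOVA F-test.

## What the generator emulates — and what it does not

`sim_config()` defaults describe a scaled-down cashmere-goat-like
population: 500 individuals (scaled from ~2,300) at 5,000 SNPs (from
~50,000), 2–5 records per individual (the source population averages ~4.2),
and four categorical fixed factors (5 flocks, 2 sexes, 6 ages, 4 years —
level counts are stand-ins, as the motivating study reports none). Trait
regimes in `goat_trait_presets()` carry the published whole-panel variance
components for the four traits, e.g. cashmere yield with
$\sigma_a^2 = 9672.55$, $\sigma_d^2 = 2049.59$, $\sigma_p^2 \approx 0$,
$\sigma_e^2 = 26699.68$ (grams$^2$). QTL effects are drawn normal and then
rescaled so the realised additive and dominance score variances equal their
targets *exactly*, giving downstream recovery tests a fixed truth. Fixed
effect level values are equally spaced offsets spanning one residual SD.
Records per individual are uniform on the configured range; flock and sex
are individual-constant while age and year advance across an individual's
records.

Genotypes are independent SNPs under Hardy–Weinberg by default; an optional
block-copying scheme adds within-block LD (each SNP copies a block template
gamete with configurable probability), since p-value ranking is more
realistic when markers tag causal loci. What the generator does **not**
emulate: pedigree structure and family clustering, selection and drift
across generations, genotyping error or missingness mechanisms, minor
allele frequency spectra shaped by ascertainment, and LD decay calibrated
to a real map. Passing tests therefore demonstrate internal correctness and
statistical behaviour under idealised sampling, not performance on a real
breeding population.

## Problem sizes used by the test-suite studies

The simulation studies in the tests use sizes chosen to make their
statistical claims detectable while staying desktop-friendly: parameter
recovery at 1,000 individuals with 3 records each over 30 seeds;
$\tau$-enrichment at 300 individuals over 30 seeds; the cross-validated
comparison of prior-weighted against plain GBLUP at 500 individuals and
2,000 SNPs over 20 replicates, with a shuffled-p-value negative control on
the same replicates. Accuracy gains under an informative prior are judged by
a paired one-sided t-test at the 5% level.

## Known limitations

* The association scan has no polygenic control; with strong structure its
  p-values are inflated (use an external mixed-model GWAS instead).
* Standard errors of variance components come from the inverse
  average-information matrix at convergence; heritability standard errors
  via the delta method are not propagated.
* Single-trait models only; no pedigree (A or H) matrices; no epistatic
  terms; two marker classes only (no multi-bin or per-SNP weighting).
* The dominance scale is tied to the hybrid coding described above;
  dominance variances are not comparable across packages without rescaling.
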