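---
title: "Estimating the genetic basis of height-mediated mate choice with GREML"
author: "AssortMate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the genetic basis of height-mediated mate choice with GREML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AssortMate)
```

## The scientific question

Couples resemble each other in height far more than chance predicts. If that
resemblance is driven by the phenotype itself — tall people preferring tall
partners — then "the height of one's partner" becomes, statistically, a
heritable trait of the *focal* individual: their genes shape their own height,
their height shapes their choice, and the partner's height inherits a genetic
signal at second hand. AssortMate implements the full estimation chain for
this idea on synthetic cohorts: genomic-relationship-matrix REML (GREML) of
"partner height" as a trait, the bivariate genetic correlation between own and
partner height, polygenic prediction of a partner's height from the focal
genotype, a couple-swap permutation that separates phenotypic assortment from
geographic/social confounding, and the closed-form theory that links the
couple correlation $r_p$ and the height heritability $h^2$ to everything else.

## Models

### Univariate GREML

For a trait $y$ on $n$ individuals with fixed effects $X$,

$$ y = X\beta + g + e, \qquad g \sim N(0, A\sigma_g^2), \qquad
   e \sim N(0, I\sigma_e^2), $$

where $A = ZZ'/M$ is the genomic relationship matrix built from
column-standardized dosages $z_{ij} = (d_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$
over $M$ markers. The equivalent marker-effects form
$y = X\beta + Za + e$ with $a \sim N(0, I\sigma_u^2)$ and
$\sigma_g^2 = M\sigma_u^2$ gives the BLUPs

$$ g = \sigma_g^2 A V^{-1}(y - X\beta), \qquad
   a = \sigma_u^2 Z' V^{-1}(y - X\beta), \qquad V = A\sigma_g^2 + I\sigma_e^2, $$

which satisfy $Za = g$ exactly (asserted in the tests to $10^{-8}$).
`fitUnivariateGREML()` maximizes the restricted likelihood with one
expectation–maximization (EM) update from an equal split of the OLS residual
variance, followed by average-information (AI) updates. The EM step never
decreases the restricted likelihood, which the test suite asserts along the
stored trace; AI steps are guarded by step-halving whenever a proposal lowers
the likelihood or leaves the parameter space.

*Numerical route.* Because $A$ is fixed across iterations, the model is
rotated onto the eigenbasis of $A$: with $A = U\Lambda U'$, the transformed
covariance is diagonal, $D = \Lambda\sigma_g^2 + I\sigma_e^2$, and every
likelihood, gradient, EM and AI evaluation costs $O(nL^2)$ after a single
eigendecomposition. This is an exact reparameterization — the restricted
likelihood is unchanged, as verified against the dense Cholesky evaluation
(`remlLogLik()`) and an independent error-contrast oracle — chosen over
per-iteration dense Cholesky solves because it makes the replicate
simulations (ten fits at $n = 4{,}000$) cheap. Convergence is declared when
the likelihood gain falls below $10^{-6}$ (cap 100 iterations); variances are
floored at $10^{-8}\,\mathrm{var}(y)$. The SE of
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ comes from the delta method on the
inverse AI matrix; fixed effects are GLS at the fitted variances.

### Bivariate GREML

Own height ($y_1$) and partner height ($y_2$) are modelled jointly with
genetic covariance $A_{12}\sigma_{g_1g_2}$ and residual covariance
$\sigma_{e_1e_2}$ applied over the overlap map (records of the same
individual). In this analysis every individual carries both traits, so all
three GRM blocks coincide and the overlap is the identity, but
`fitBivariateGREML()` accepts arbitrary blocks and overlap pairs. The six
components are estimated by AI-REML on the dense model, initialized from the
per-trait univariate fits with a damped first step; proposals whose genetic
or residual 2x2 covariance matrix is not positive semidefinite are rejected
by the same step-halving. Correlations are derived as

$$ r_G = \frac{\sigma_{g_1g_2}}{\sqrt{\sigma_{g_1}^2\sigma_{g_2}^2}}, \quad
   r_E = \frac{\sigma_{e_1e_2}}{\sqrt{\sigma_{e_1}^2\sigma_{e_2}^2}}, \quad
   r_P = \frac{\sigma_{g_1g_2}+\sigma_{e_1e_2}}
             {\sqrt{(\sigma_{g_1}^2+\sigma_{e_1}^2)(\sigma_{g_2}^2+\sigma_{e_2}^2)}}, $$

with delta-method SEs from the 6x6 inverse AI matrix. $r_P$ can also be read
directly as the covariate-adjusted Pearson correlation of the two traits;
both routes are available and the tests compare them on simulated cohorts.

### Closed-form assortment theory

For a standardized phenotype $P = A + E$ under the ante-dependence chain
$A \rightarrow P \rightarrow P_{\mathrm{partner}}$ (genes act on the
partner's phenotype only through one's own phenotype):

* expected mate-choice heritability $h^2_{P_m} = r_p^2\,h^2$;
* expected breeding-value correlation among mates $m = r_p\,h^2$;
* heritability under random mating
  $h_0^2 = h^2(1-m)/(1-mh^2)$, i.e. removing the assortment-generated
  (directional linkage disequilibrium) share of the additive variance,
  $V_{A0} = (1-m)V_{A,eq}$, at constant environmental variance;
* the percent inflation $100\,(h^2 - h_0^2)/h_0^2$.

A note on the $h_0^2$ denominator: the additive-variance accounting
$h_0^2 = V_{A0}/(V_{A0} + V_E)$ with $V_E = 1 - h^2$ forces the $1 - mh^2$
form, which is what the package implements; a $1 + mh^2$ denominator is
algebraically inconsistent with that bookkeeping (at $h^2 = 0.8$, $m = 0.2$
it would give 0.55 rather than 0.76) and is not used. At $h^2 = 0.8$ and
$m = 0.2$ the implemented form gives:

```{r}
randomMatingH2(0.8, 0.2)
heritabilityIncreasePct(0.8, randomMatingH2(0.8, 0.2))
```

Two evaluations of the expected mate-choice heritability are worth keeping
apart: at the raw couple correlation 0.26 it is
`expectedMateChoiceH2(0.26, 0.8)` = `r expectedMateChoiceH2(0.26, 0.8)`,
while at the covariate-adjusted correlation 0.232 it is
`r round(expectedMateChoiceH2(0.232, 0.8), 3)`. The adjusted value is the one
comparable to a mixed-model estimate that already conditions on the same
covariates; the package exposes both rather than privileging either.

## The synthetic cohort generator

`simulateCohort()` produces the statistical situation the estimators assume,
with every default fixed once and used unchanged throughout the tests:

* **Genotypes** — biallelic SNP dosages Binomial$(2, p_j)$,
  $p_j \sim U(0.05, 0.5)$: Hardy–Weinberg proportions with the 5 % MAF floor
  of the QC protocol. Missing genotypes are injected only on request
  (default rate 0) to exercise QC.
* **Heights** — $P = A + E$ with $A$ a weighted sum over a causal 10 % of
  SNPs, rescaled so the realized $\mathrm{var}(A)/\mathrm{var}(P)$ equals
  the requested $h^2$; within-sex SD 6.5 cm and a +13 cm male shift,
  roughly the values seen in UK adults. Sex enters the estimators only as a
  fixed effect, so only the mean shift matters.
* **Couples** — each sex receives a matching score, the within-sex
  standardized height plus Gaussian noise of variance $(1-r)/r$, and the
  sexes are paired by score rank. Rank pairing makes the two scores
  comonotone, so the couple height correlation is approximately $r$; a short
  calibration loop rescales the working $r$ until the realized correlation
  is within 0.02 of the target. The mechanism depends on phenotype only,
  which is exactly the ante-dependence assumption of the theory; the
  observed breeding-value correlation among mates then matches
  $r_p h^2$ (a test asserts this within $3/\sqrt{n}$). The regression form
  $P_m = bP + E_m$ constrains only the first two moments, so any pairing
  mechanism with the right correlation is admissible; noisy rank-matching
  was chosen because it is simple, deterministic given the seed, and
  calibratable.
* **Covariates** — both partners share a household id; birthplaces scatter
  (SD 20 km) around one of 25 cluster centres on a 600 km grid shared
  within couples; ages are couple-correlated at 0.9 (mean 55, SD 8);
  Townsend deprivation is a household value plus individual noise. These
  exist so the couple-swap has dependence to destroy.

What the generator does **not** emulate: multi-generation assortment (no
directional LD accumulates between unlinked loci — equilibrium claims are
handled analytically, not by forward simulation), linkage and LD structure
along the genome, genotyping platform artefacts beyond a platform label,
X-chromosome markers, and genetic or environmental *group* assortment
(couples share geography but genotypes are panmictic, so geographic genetic
structure is absent unless a test constructs it explicitly). Passing tests
therefore demonstrate correctness of the estimation chain under
phenotype-driven assortment, not robustness to the confounds real cohorts
carry — probing those confounds is precisely the job of the permutation
module.

## Quality control

SNPs are filtered in the order missingness (> 2 %), platform missingness
bias (Fisher exact $p < 10^{-100}$), Hardy–Weinberg exact test
($p < 10^{-50}$), minor allele frequency (< 0.05, computed on the analysis
subset); samples at missingness > 5 % or autosomal heterozygosity more than
3 SD from the sample mean; phenotypes strictly more than 3 SD from their
gender mean, means and SDs taken on the input set in a single pass. The
filter order is a package decision (it changes surviving counts only
marginally); each filter is idempotent and every report row satisfies
excluded + retained = input. The HWE test enumerates heterozygote counts
conditional on allele counts in log space (no mid-p correction — the plain
exact test is the conservative default), and agrees with the chi-square
test within 10 % relative p at counts in the thousands. The heterozygosity
cut is symmetric at ±3 SD: the upstream-cohort procedure it stands in for
is not reproducible, and a two-sided cut also catches genotyping failure.

## Permutation control

`swapMales()` orders couples lexicographically by (female height, male
height) and exchanges the males of successive couples, leaving the last
couple of an odd count unchanged. The sort key is one reading of "ordering
couples by both heights"; ties are broken by stable sort order. Successive
couples in the sort are nearly identical in height, so the couple height
correlation is preserved up to $o(1)$ while household, geography, age and
deprivation pairings are broken. Dependence is measured by Pearson
correlation (continuous) or plug-in mutual information with a permutation
p-value over 1,000 female-side permutations (categorical); the plug-in MI
estimator is biased upward, but the permutation null carries the same bias,
so no correction is applied.

## Choices made where the design was genuinely open

* PCA operates on the GRM of an LD-pruned marker set (window 50, step 5,
  $r^2 < 0.2$ — conventional values; only the pruned marker count, not the
  parameters, is constrained by the analysis this mirrors), and
  eigenvectors are unit-norm with the largest-magnitude loading positive.
* The GRM divisor is $M$ with mean imputation of missing genotypes, which
  keeps $\sigma_g^2 = M\sigma_u^2$ exact; per-pair non-missing divisors
  would break the $ZZ'/M$ algebra that the SNP-BLUP identity relies on.
* Both couple members serve as focal individuals (two focal records per
  couple); the GRM indexes each individual once.
* A couple is dropped whenever either member fails any sample or phenotype
  filter.
* GWAS effects are ordinary least squares with covariates projected out of
  phenotype and genotype, on a greedily constructed unrelated subset
  (iteratively dropping the individual with the most $r > 0.0625$ ties).
* In the bivariate fitter the first step is a damped AI step seeded from
  univariate EM-REML fits: a true EM step for covariance components needs
  $A^{-1}$, which a GRM with $M < n$ does not have.

## Problem sizes and runtime

The package's reference simulation for the mate-choice heritability runs
replicate cohorts of 2,000 couples by 5,000 SNPs (ten in the test suite, twenty in the acceptance run) (4,000 focal records
per fit) — large enough that the per-replicate SE of $\hat h^2$ is ~0.026
and the replicate mean lands within ~0.01 of the expected
$r_p^2 h^2 = 0.041$, small enough to complete in minutes on one core. The
breeding-value check uses 10,000 couples by 500 SNPs. Unit and property
tests run at $n$ of a few hundred with tolerances stated per test (brute
force oracles at $n \le 30$ to $10^{-8}$; Monte-Carlo recoveries within 2–3
SEs).

## Known limitations

* Single-generation simulation: equilibrium quantities (e.g. $h_0^2$) are
  analytic, never simulated.
* The bivariate fitter is dense ($O((n_1+n_2)^3)$ per iteration) and meant
  for desk-scale cohorts; the univariate spectral route does not carry over
  once two covariance structures are present with partial overlap.
* Delta-method SEs are asymptotic and degrade near variance boundaries
  (e.g. $\hat\sigma_{g}^2$ at its floor, or $|r_G|$ near 1, where the
  estimate is clamped into $[-1, 1]$).
* `hweExactTest` and the Fisher platform test are exact but two-sided by
  probability-ordering; one-sided variants are not exposed.
* The X chromosome, imputation dosages and multi-allelic sites are out of
  scope; multi-allelic handling is exclusion at QC.
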