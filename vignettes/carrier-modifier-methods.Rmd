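---
title: "Modelling genetic modifiers of cancer risk in mutation carriers"
author: "carrierhr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic modifiers of cancer risk in mutation carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierhr)
```

## The estimation problem

Women carrying pathogenic BRCA1 or BRCA2 variants face high lifetime
breast and ovarian cancer risks, and common SNPs can shift those risks
further.  Estimating such modifier effects is complicated by how
carrier cohorts come into being: families reach genetic clinics
*because* cancer occurred in them, so affected carriers are strongly
over-represented and relatives cluster within the sample.  A cohort
that over-samples cases distorts a prospective survival likelihood but
leaves the distribution of *genotypes given phenotypes* untouched,
because recruitment acts on phenotype only.  `carrierhr` therefore
maximises the retrospective likelihood

$$
\sum_i \log \frac{L_i(g_i)\, p_{g_i}(c_i)}
                 {\sum_g L_i(g)\, p_g(c_i)},
$$

where $p_g(c)$ is the Hardy–Weinberg genotype prior at the
minor-allele frequency $q_c$ of carrier $i$'s country stratum $c$, and
$L_i(g)$ is the phenotype likelihood under genotype $g$.  Both the
effect parameters and the per-stratum allele frequencies are estimated
jointly; fixing the frequencies externally is available
(`q_fixed`) but not the default, since misspecified frequencies
propagate directly into the genotype prior.

## The phenotype model

Each carrier's cancer hazard follows proportional hazards on a yearly
grid (default ages 18–80, hazards piecewise constant on $[t, t+1)$):
$\lambda_g(t) = \lambda_0(t)\, r_g(t)$ with
$r_g(t) = e^{\beta z_g}$ for the per-allele (trend) model
($z_g = g$), or free heterozygote/homozygote log-hazard ratios
(the 2-df model).  The proportional-hazards assumption is testable by a
genotype-by-age interaction, parameterised as
$\beta(t) = \beta_0 + \beta_1 (t - 40)/10$ — per decade, centred at age
40, near the median censoring age of typical carrier cohorts, which
keeps $\beta_0$ interpretable and the two parameters weakly correlated.

An unaffected carrier followed to age $T$ contributes
$S_g(T) = \exp(-\sum_{u<T}\lambda_0(u) r_g(u))$; a carrier affected at
age $t$ contributes the density form $S_g(t)\,\lambda_0(t) r_g(t)$.
Using the density rather than the interval probability
$S_g(t)(1 - e^{-\lambda_g(t)})$ is a stated convention; both are
defensible for yearly hazards of the magnitudes seen here (below 0.05)
and the difference is second order in $\lambda$.

### The incidence constraint

The baseline $\lambda_0$ is not a free parameter.  Carrier-average
age-specific incidences are supplied externally (they are estimable
from population studies, unlike the cohort's own biased case load), and
$\lambda_0$ is chosen so that the genotype-averaged hazard among
survivors reproduces the supplied curve $\lambda^*(t)$ at every age.
Forward in age, with $S_g(a_{\min}) = 1$:

$$
\lambda_0(t) \;=\; \lambda^*(t)\,
\frac{\sum_g p_g S_g(t)}{\sum_g p_g S_g(t) r_g(t)},
$$

then update each $S_g$.  The defining conservation law — genotype-
averaged hazard equals $\lambda^*$ at every age — is enforced to
numerical precision and tested on random configurations (observed
error is at machine precision, far below the 1e-10 requirement).
Baselines are stratum- and cohort-band-specific and are recomputed at
every parameter update, since both $\beta$ and $q_c$ enter the
constraint.  Incidence curves may be keyed by birth-cohort band
(`cohort_band` column, `"YYYY-YYYY"` ranges); each carrier's band is
resolved from her birth year.

The packaged `default_incidence()` curves are illustrative
piecewise-constant constants with cumulative breast cancer risk to age
70 of roughly 55% for BRCA1 — the right penetrance range, but not
estimates; analyses of real data must supply their own curves.

## Censoring rules

For the single-disease (breast) analysis a carrier is followed to the
first of: breast cancer diagnosis, ovarian cancer diagnosis, bilateral
prophylactic mastectomy, or last observation.  Only a first breast
cancer counts as affected; carriers censored at ovarian cancer are
unaffected.  In the competing-risks analysis follow-up ends at the
first cancer of either type, which is counted for its own disease; the
breast risk period is additionally truncated at mastectomy and the
ovarian one at oophorectomy.  Ages are integer years; ties among
candidate censoring ages resolve in the fixed priority breast >
ovarian > mastectomy > last observation (a stated convention — the
alternatives differ only on exact ties of integer ages).  Surgery dates
must already be converted to ages in the input.

## Competing risks

Breast and ovarian cancer are modelled as conditionally independent
cause-specific hazards given genotype, with separate log-HRs and each
disease's baseline constrained to its own incidence curve.  The
survival factor uses both cumulative hazards at their disease-specific
end ages.  In the forward constraint both diseases share the joint
survival weights $p_g S_g(t)$ (with $S_g$ the joint survivor): supplied
population incidences are measured among carriers free of both
cancers, so the at-risk weighting should deplete mass lost to either
disease.  When one disease's curve is identically zero this reduces
*exactly* to the single-disease recursion, and the fit reduces to the
single-disease fit (a tested identity); the uninformative effect
parameter is then fixed at zero and reported as absent.

## Tumour-subtype effects with missing labels

ER-positive and ER-negative breast cancers are treated as competing
sub-causes with shared baseline: the subtype-specific hazard is
$\lambda_0(t)\,\pi_s(t)\,e^{\beta_s z_g}$, where $\pi_s(t)$ is the
age-indexed fraction of carrier tumours of subtype $s$ (a required
input table; the packaged `default_subtype_props()` step functions —
BRCA1 tumours predominantly ER-negative, BRCA2 predominantly
ER-positive, with the positive fraction rising after 50 — are
illustrative placeholders and user-replaceable).  The overall genotype
relative risk $r_g(t) = \sum_s \pi_s(t) e^{\beta_s z_g}$ feeds the
baseline constraint.  A case with known subtype contributes her
subtype's cause-specific density; a case with unknown subtype
contributes the sum over subtypes, which is the correct likelihood
when missingness is unrelated to subtype given the observed data
(missing at random).  Subtype heterogeneity is tested by a Wald
contrast of $\beta_{pos}-\beta_{neg}$ on the joint family-robust
covariance.  Degenerate inputs are handled explicitly: a subtype with
zero proportion at all ages has its parameter dropped (reported
absent), and constraining a common effect across subtypes collapses
the model onto the single-disease fit (a tested identity).

## Variance estimation

Relatives share genotypes, so per-carrier score contributions are not
independent.  All reported confidence intervals and Wald tests use the
cluster sandwich $A^{-1} B A^{-1}$ with $A$ the observed information
and $B$ the outer product of within-family score sums;
likelihood-ratio tests (trend, 2-df, heterogeneity, age interaction)
remain model-based, as is standard practice.  No finite-cluster
correction is applied by default; the $G/(G-1)$ factor is available
behind a flag.  The signature that clustering is honoured is algebraic:
duplicating every carrier *within* her family leaves the robust
covariance unchanged while halving the model-based covariance, and this
is tested exactly.  In simulated sibships of four the clustering
penalty concentrates in the allele-frequency parameter (robust/naive
SE ratio around 1.5), while the log-HR's score sums are only weakly
correlated in this design — the corresponding test therefore checks
the allele-frequency component.

## Numerical choices

Optimisation is quasi-Newton (BFGS) on $(\beta, \mathrm{logit}\,q_c)$
with central finite differences (step $10^{-5}$) and relative
log-likelihood convergence tolerance $10^{-9}$; non-convergence is
flagged on the result, never silent.  The logit transform keeps
frequencies in $(0,1)$ without constraints, and the reported
covariance of $\hat\beta$ is invariant to that reparametrisation.
Likelihoods are computed on aggregated cells — carriers with identical
(stratum, band, status, end ages, subtype, genotype) tuples share one
likelihood evaluation — so a fit costs the same for 300 or 30,000
carriers; per-carrier scores for the sandwich are recovered through
the cell map.  Under the null of no genotype effect the phenotype
factor cancels and the retrospective likelihood reduces to the HWE
multinomial, so the null used by the trend and 2-df LRTs has the
closed-form solution $\hat q_c$ = sample allele frequency.  Whether
the trend P-value should be a score, Wald or LR test is
underdetermined; the package reports the LRT as `p_trend` and robust
Wald tests per parameter, and the two agree closely at the sample
sizes where either is trustworthy.  Records with a missing dose for
the analysed SNP are dropped per SNP (complete case per SNP), logged.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the estimator
assumes, not any particular real cohort.  Families are sibships of 1–4
sisters (uniform); founder alleles are drawn at the stratum frequency
and siblings inherit from shared simulated parents, inducing the
within-family genotype correlation the sandwich must absorb.  Life
histories are simulated on the same discrete yearly grid as the
analysis — event probability $1-\exp(-\lambda)$ per year, cause and
subtype drawn proportionally to the cause-specific hazards — from
genotype-specific hazards $\lambda_0 r_g$ whose genotype average
reproduces the configured incidence curves, so recovery checks isolate
ascertainment correction rather than baseline misspecification.  (The
analysis event factor is the density form; this convention mismatch
biases the log-HR by roughly $\lambda\beta/2 \approx 0.002$ —
negligible against the testing bands.)  Prophylactic surgeries occur
as independent yearly Bernoulli events from age 30; recruitment draws
probands with probability proportional to configurable weights
(default 5:1 affected:unaffected, the clinic-ascertainment regime the
estimator exists to withstand), includes each proband's relatives with
probability 0.5, and requires age ≥ 18 at interview.  ER labels are
deleted completely at random at the configured rate (default 30%).

What the generator does *not* emulate — multi-generation pedigrees,
calendar-period incidence trends, genotyping error, mutation-position-
specific penetrance, and missingness mechanisms tied to subtype — means
passing recovery tests demonstrate correctness of the estimator under
its own assumptions, not robustness to their violation in real data.

Validation sizes used by the test suite and acceptance script were
chosen to keep Monte-Carlo error comfortably below the decision bands:
50 cohorts of ≈3,000 carriers for HR recovery (truth HR 0.87 under
5× oversampling, tolerance ±0.03 on the log scale), 50 cohorts for
ER-negative recovery (truth 0.81, tolerance ±0.04, 30% missing
labels), and 500 null cohorts of ≈1,000 carriers for the exact
binomial 99% calibration check of the trend test at $\alpha = 0.05$.

## Known limitations

* The likelihood uses each carrier's own phenotype only; genotypes of
  untyped relatives contribute nothing (no full pedigree likelihood).
* Conditional independence of breast and ovarian risks given genotype
  excludes shared frailty beyond the modifier SNP.
* Only two tumour subtypes are supported, with proportions supplied as
  input rather than estimated.
* The incidence constraint assumes the supplied curves are themselves
  unbiased for the carrier population (and the correct cohort bands).
* Allele-frequency estimation assumes HWE within stratum; gross
  departures are a QC failure, not a model feature.
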