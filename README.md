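# carrierhr

Retrospective-likelihood association analysis for common genetic
variants that modify breast and ovarian cancer risk in **BRCA1/BRCA2
mutation carriers**.

## The problem

Carrier cohorts are assembled through cancer genetics clinics, so
affected women are heavily over-represented and relatives of the same
family appear together.  A naive survival analysis of such data gives
biased hazard-ratio estimates.  `carrierhr` implements the standard
remedy used in carrier modifier studies: model the **retrospective
likelihood of the observed genotypes conditional on the disease
phenotypes**,

```
L_i = P(g_i | phenotype_i) = L_i(g_i) p_{g_i} / sum_g L_i(g) p_g ,
```

where `p_g = ((1-q)^2, 2q(1-q), q^2)` is the Hardy–Weinberg genotype
prior at minor-allele frequency `q` and `L_i(g)` is the phenotype
likelihood under a proportional-hazards model
`lambda_g(t) = lambda_0(t) r_g(t)` with genotype relative risk
`r_g(t) = exp(beta z_g)` (per-allele *trend* model, `z_g = g`, or free
heterozygote/homozygote effects).  Because the likelihood conditions on
phenotype, recruitment that depends on phenotype — however aggressive —
cancels out.

The baseline hazard is not free: it is constrained so that the
genotype-averaged hazard among survivors reproduces an externally
supplied carrier incidence (penetrance) curve `lambda*(t)` at every
age, computed forward in age:

```
lambda_0(t) = lambda*(t) * sum_g p_g S_g(t) / sum_g p_g S_g(t) r_g(t),
S_g(t) = exp(-sum_{u<t} lambda_0(u) r_g(u)).
```

On top of this core the package provides:

* **competing risks** — cause-specific hazard ratios for breast and
  ovarian cancer estimated simultaneously, each baseline constrained to
  its own incidence curve, with per-disease censoring at prophylactic
  mastectomy/oophorectomy;
* **tumour-subtype effects** — simultaneous hazard ratios for ER-positive
  and ER-negative breast cancer with missing-at-random subtype labels,
  and a Wald test of their difference;
* **family-cluster robust variance** — sandwich covariance with scores
  summed within families, used for all reported CIs and Wald tests;
* **genotyping QC** — per-sample missingness (≥20% of SNPs typed, i.e.
  5+ of 26), per-study call rate (strictly >95%), duplicate concordance
  (≥98%), cross-centre test-plate consistency (more than one discordant
  sample fails), per-study Hardy–Weinberg tests on unrelated subjects;
* **a synthetic cohort generator** — clinic-ascertained carrier families
  with HWE founder genotypes, sibling genotype sharing, genotype- and
  subtype-specific piecewise-constant yearly hazards, surgery censoring
  and affected-oversampled recruitment, so the whole pipeline is
  testable without any external data.

## Worked example

Simulate a clinic-ascertained BRCA1 cohort in which each copy of the
minor allele multiplies the breast cancer hazard by 0.87, with affected
carriers recruited at five times the rate of unaffected ones, then fit
the per-allele model:

```r
library(carrierhr)

cfg <- sim_config(n_families = 1500, maf = 0.25,
                  beta_breast = log(0.87),
                  w_affected = 5, w_unaffected = 1, seed = 60101)
rec <- simulate_cohort(cfg)
summarize_cohort(rec)
#> Carrier cohort summary
#>   carriers: 1402 unaffected, 847 breast cancer
#>   person-years follow-up: 93322
#>   median age at censure: 41 (IQR 33 to 49)

fit_snp(rec, "rs0001")
#> Retrospective-likelihood fit: rs0001 (BRCA1, trend model)
#>   2249 carriers (847 affected / 1402 unaffected), 0 dropped for missing genotype
#>   trend            HR 0.869 (95% CI 0.766 to 0.987)  robust SE 0.065
#>   allele frequency: ALL=0.2398
#>   p_trend: statistic 4.483 (df 1), p = 0.0342
#>   loglik -1887.7528 (null -1889.9941), converged: TRUE
```

The estimated per-allele HR (0.869 in this cohort; individual cohorts
scatter around the generative 0.87 and averaged over replicates the
estimator is unbiased, see the test suite) comes with a
family-cluster robust 95% CI, a 1-df
likelihood-ratio trend test, and the jointly estimated allele
frequency.  Despite the 5× oversampling of affected carriers, no
ascertainment correction factor is needed: conditioning on phenotype
removes it.  `fit_competing()`, `fit_subtype()`,
`test_heterogeneity()`, `test_age_interaction()`,
`test_group_difference()` and `exclude_prevalent()` cover the extended
and sensitivity analyses; `run_pipeline()` chains simulation/input, QC
and fitting from a single (YAML) configuration, and
`inst/scripts/carrierhr.R` exposes the same stages as shell
subcommands.

The packaged incidence curves (`default_incidence()`) and ER-subtype
proportions (`default_subtype_props()`) are illustrative synthetic
constants; real analyses should supply cohort-specific tables via
`read_incidence()`.

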