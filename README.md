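# lcasub

Latent class subgrouping of multi-domain patient data.

`lcasub` is an R package for identifying patient subgroups from mixed
questionnaire and clinical-examination data with latent class analysis
(LCA). It was built around the methodology used in multi-domain low back
pain subgrouping studies, where ~100 baseline variables spanning six
health domains (activity, contextual factors, pain, participation,
physical impairment, psychology) are clustered either all at once
(*single-stage* LCA) or via a *two-stage* pipeline: one LCA per health
domain, hard assignment of every patient to a domain category, then a
second LCA over the six categorical domain memberships. It is aimed at
biostatisticians and clinical researchers who need a reproducible,
scriptable version of that workflow, including its model-selection rules
and solution-comparison diagnostics.

## The model

The core is a finite mixture for mixed nominal/ordinal/continuous
indicators under local independence. Patient *i* with responses
*y*<sub>*i*1..J</sub> has likelihood

    f(y_i) = Σ_k π_k Π_{j observed} f_j(y_ij | k)

where `π_k` are class weights, categorical indicators have
class-conditional category probabilities `θ_jkc`, and continuous
indicators are Gaussian with class means `μ_jk` and a per-variable
variance (pooled across classes by default). Missing entries are simply
skipped in the product (ignorable missingness; nothing is imputed).
Estimation is EM from a seed-determined random start; model comparison
uses BIC = −2·loglik + p·log(n).

On top of that engine the package implements the study workflow:

* **Model search** (`run_search`): class counts 1..12, ten seeded random
  restarts per count, restart retention by the *most-consistent-BIC* rule
  (modal BIC value after rounding to 2 decimals, minimum BIC as
  fallback), and a *starting model* chosen by walking up the class counts
  while BIC keeps decreasing by at least 1%.
* **Two-stage pipeline** (`run_two_stage`): per-domain LCAs, modal
  domain-category assignment, and a second-stage search over the derived
  all-categorical dataset.
* **Diagnostics**: posterior-certainty summaries (median maximum
  posterior, counts below 0.70 and multi-membership above 1/3),
  severity-normalized profile matrices, feature detection (≥30% spread,
  concordant profiles), qualitative-vs-quantitative profile comparison,
  subgroup-size checks (5% rule with the 3–5% relaxation), and flagged
  membership cross-tabulations with agreement statistics (greedy 1–1
  matching, adjusted Rand index).
* **Synthetic cohorts** (`generate_cohort`): configurable cohorts with
  planted class structure (default: 928 patients, 112 mixed variables in
  six domains with category counts 7, 7, 7, 7, 6, 8, ~5% MCAR cells), so
  every stage is testable although the original cohort was never
  deposited.

## Worked example

```r
library(lcasub)

spec <- cohort_spec(n = 400, domains = list(
    pain = list(n_categories = 3, nominal = 3, nominal_levels = 3,
                ordinal = 1, ordinal_levels = 4, continuous = 1),
    psychology = list(n_categories = 3, nominal = 3, nominal_levels = 3,
                      ordinal = 1, ordinal_levels = 4, continuous = 0)),
  G = 3, delta = 0.85, missing_rate = 0.05, seed = 42)
co <- generate_cohort(spec)

search <- run_search(co$data, K_max = 5, n_restarts = 4, base_seed = 42)
search
#> <lca_search>
#>   K   BIC
#>   1   6547.36
#>   2   5626.04
#>   3   4939.40  <- starting model
#>   4   5025.17
#>   5   5125.37

fit <- search_fit(search, 3)
posterior_summary(fit)
#> <posterior_summary> n = 400
#>  median max posterior: 1.00 (IQR 1.00-1.00)
#>  max posterior < 0.70: 4 (1%)
#>  posterior > 0.33 for more than one subgroup: 4 (1%)

adjusted_rand_index(fit$assignments, co$truth$class)
#> [1] 0.9699068
```

The search table shows BIC falling by well over 1% up to the three
planted classes and rising after, so the 1%-decrease walk stops at K = 3;
the posterior summary says assignment is essentially certain (median
maximum posterior 1.00), and modal assignments agree with the planted
classes at ARI 0.97.

Comparing two subgroup solutions uses the flagged cross-tabulation. The
package ships the published 7×9 membership comparison of a single-stage
(rows) against a two-stage (columns) solution on 928 patients:

```r
ct <- published_crosstab()
ct
#>         TS1  TS2  TS3  TS4  TS5  TS6  TS7  TS8  TS9 Total
#> SS1    26^c 79^a 27^c 36^b    0 14^d    3  6^d    1   192
#> SS2       0 69^a    4    2    0 31^b 29^b 19^b    0   154
#> SS3   113^a    3 13^d    4    2    0    0    1    0   136
#> ...
#> Total   219  161  127  113   71   69   74   45   49   928

crosstab_agreement(ct)$ari
#> [1] 0.2061793
```

Flag `a` marks each row's largest cell, `b` a column maximum, `c`/`d`
cells above 10% of their row/column margin. SS3 concentrates 113 of its
136 patients (83%) in TS1 — nearly a subset — while the overall adjusted
Rand index of 0.21 shows the two solutions group patients quite
differently despite similar clinical descriptions.

A YAML-configured command-line pipeline
(`inst/scripts/lcasub.R --config run.yml`) chains
simulate → preprocess → search → two-stage → diagnose and writes every
artifact with an MD5 manifest.

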