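---
title: "Latent class subgrouping of multi-domain patient data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class subgrouping of multi-domain patient data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcasub)
```

This vignette is the package's own account of the statistics it
implements: the mixture model and its assumptions, the estimation and
model-selection machinery, the two-stage pipeline, the diagnostics, the
synthetic-cohort generator, and the numerical and design choices that were
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A cohort of $n$ patients answers $J$ mixed-type items. `lcasub` fits a
finite mixture with $K$ latent classes under *local independence*: within
a class, all indicators are independent, so a patient's likelihood is

$$f(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j \in \mathrm{obs}(i)} f_j(y_{ij} \mid k),$$

with class weights $\pi_k$, and per indicator:

* **nominal and ordinal** variables: a full conditional probability table
  $\theta_{jkc}$ over the $C_j$ declared categories. Ordinal variables are
  deliberately modelled as unordered multinomials; their ordering is used
  only in summaries (conditional means via equidistant integer scores
  $1..C_j$) and profile normalization. An adjacent-category or
  cumulative-logit parameterization would impose structure that the
  methodology this package implements never specifies, so equivalence of
  BIC values with proprietary LCA software that treats ordinal items
  specially is not claimable and not attempted.
* **continuous** variables: Gaussian with class means $\mu_{jk}$ and, by
  default, one variance $\sigma^2_j$ *pooled across classes*. Pooling
  costs $K-1$ parameters less per variable and avoids the classic
  degeneracy where a class variance shrinks onto a single point;
  class-specific variances are available via
  `variance_mode = "class_specific"`.

Missing entries are skipped in the product: each row contributes the
mixture density of its observed cells only. This is the ignorable
(missing-at-random) likelihood; nothing is imputed. A patient with *no*
observed cell carries no information and is rejected at dataset
construction (`read_lca_dataset()` drops such rows with a message, the
analogue of excluding patients with completely missing data).

## Estimation

`fit_em()` runs EM:

* **Initialization.** Per-row responsibilities are drawn from a symmetric
  Dirichlet(1) using the caller's seed, followed by an M step. Every fit
  is a pure function of (data, K, seed, settings); two calls with the
  same arguments return identical objects.
* **E step** in the log domain (`log-sum-exp`), so small densities cannot
  underflow. Posterior rows sum to 1 to $10^{-9}$.
* **M step**: weighted relative frequencies / means / variances.
  Degeneracy guards: every $\theta$ cell is floored at $10^{-6}$ and the
  row renormalized; every variance is floored at $10^{-6}$ times the
  variable's sample variance. The floors prevent $-\infty$ log-likelihoods
  from rare cells while perturbing non-degenerate estimates by amounts
  far below sampling error.
* **Convergence** when the relative log-likelihood change falls below
  $10^{-8}$, capped at 1000 iterations; hitting the cap returns
  `converged = FALSE` with a warning (the fit is still usable — this is
  typical for over-parameterized models drifting along a likelihood
  ridge). The log-likelihood path is stored and is non-decreasing, which
  the test suite asserts on every fit it makes.
* **Label canonicalization**: classes are relabelled in descending
  $\pi_k$ on return, so restarts that reach the same optimum agree up to
  numerics.
* A class whose total responsibility collapses below $10^{-6}$ raises a
  `lcasub_class_collapse` warning rather than being silently
  renormalized; the restart machinery records it.

Free parameters for BIC: $(K-1) + \sum_{\mathrm{cat}\, j} K(C_j-1) +
\sum_{\mathrm{cont}\, j} (K+1)$ (pooled) or $2K$ (class-specific).

## Model search: restarts and the starting model

For each class count, `fit_with_restarts()` runs ten (default) seeded
restarts, with restart seeds `base_seed + 1..n_restarts`. The retained
fit follows the *most-consistent-BIC* rule: BIC values rounded to two
decimals are tallied; a unique modal value with multiplicity at least two
wins (the best-log-likelihood fit attaining it is kept); otherwise — all
distinct, or several values tied at maximal multiplicity — the minimum
BIC wins. Two decimals separates genuine optima: distinct local optima of
a 900-patient likelihood differ in BIC by far more than 0.01, while the
same optimum reached twice agrees to much better than that. Note the rule
deliberately prefers a *reproducible* optimum over a lower one-off BIC,
on the logic that a value found repeatedly is the dominant basin, whereas
a singleton minimum may be an unreplicable artifact.

`select_starting_model()` walks $K = 2, 3, \ldots$ while
$\mathrm{BIC}(K) \le 0.99\,\mathrm{BIC}(K-1)$ and stops at the first
failure; the starting model is the last $K$ reached, capped at the global
BIC argmin if a non-monotone table would let the walk overshoot it. The
cap resolves an interaction the 1%-decrease rule leaves undefined for
non-monotone tables, and guarantees the starting model never has a BIC
above the minimum among the smaller models. The *preferred* model is
deliberately left to the analyst: choosing it is a consensus judgement
informed by the diagnostics below, not an automated rule, so
`lca_search` objects carry `preferred_K = NA` until set.

`run_search()` offsets each class count's restart base by
`(K-1) * n_restarts` so that all restart seeds across a search are
distinct; the entire search is reproducible from `(data, settings,
base_seed)`.

## The two-stage pipeline

`run_two_stage()` fits one LCA per health domain (class counts fixed by
the caller or searched per domain), assigns each patient to the domain
category with the largest posterior (*modal*, i.e. hard assignment), and
then searches class counts over the derived dataset of one nominal
variable per domain. The second-stage codebook always declares $C_d$
levels per domain even if a category was never modally assigned (the
empty level is retained and logged). Hard assignment between stages is
exactly the design being studied; it is also its known weakness — the
certainty of first-stage membership is discarded. A patient missing every
variable of one domain is still assigned (their first-stage posterior
reduces to the class weights); no minimum-posterior screen is applied
between stages, since none is part of the methodology.

Because the second stage sees only six categorical variables, its
parameter count is always far below a single-stage model on the same
cohort, which is the parsimony argument for the design; the test suite
checks this inequality across class counts on the study-scale template.

## Diagnostics

* `posterior_summary()`: median and IQR of each patient's maximum
  posterior (1.00 = no uncertainty), the count with maximum posterior
  below 0.70, and the count with posterior above 0.33 (one third) for
  more than one class. Both thresholds are strict; the multi-membership
  threshold is implemented as $1/3$ exactly, so a row exactly uniform
  over three classes is *not* counted (0.3333... would spuriously exceed
  a literal 0.33).
* `normalized_profile()`: variables × classes scores in $[0,1]$, higher
  always meaning more severe. Continuous variables are min-max scaled by
  their declared range, ordinal variables by equidistant integer scores;
  nominal variables need either numeric severity scores in their
  `recode_map` or a declared `severe_level` (the profile then shows that
  level's conditional probability) and are otherwise excluded with a
  warning — a nominal variable without any severity information has no
  defensible place on a severity profile. Variables declared
  `lower_worse` are reversed ($1-x$), an involution.
* `detect_features()`: a *feature* is a group of variables with spread
  (max − min class score) at least 0.30 each and concordant profiles.
  Concordance is operationalized as pairwise Spearman rank correlation of
  the class-score vectors at ≥ 0.6 — rank-based so that "very minor
  crossings" in level do not break a group, with the threshold excluding
  variables that order the classes substantially differently. Grouping is
  greedy in profile order against all current members, which makes the
  result deterministic and label-permutation invariant. Each group is
  classified `quantitative` if for every pair of classes the member-wise
  differences share one sign (one profile dominates), else `qualitative`
  (profiles cross).
* `subgroup_size_check()`: modal-assignment shares below 5% are flagged;
  shares in 3–5% are conditionally acceptable when the class's
  distinguishing feature variables (those on which it attains the extreme
  normalized score) include any caller-named variable known to be
  under-represented in the sampled population; below 3% is always
  flagged.
* `crosstab()` flags each cell of a joint membership table: `a` row
  maximum, `b` column maximum (if not `a`), `c` more than 10% of the row
  margin, `d` more than 10% of the column margin only, with precedence
  `a > b > c > d` making flags mutually exclusive. The published 7×9
  table that ships with the package prints dual flags on some cells and
  single flags on others under footnotes that are contradictory as
  printed (one cell exceeding 10% of both margins carries both `c` and
  `d`, another carries only `c`; one column maximum also carries `d`);
  the exclusive precedence reproduces every single-flag cell exactly and
  resolves the dual-flag cells to their dominant flag.
* `crosstab_agreement()`: per row/column spread (nonzero cells, share in
  the largest cell), percent agreement under greedy one-to-one matching
  of largest cells, and the adjusted Rand index computed directly from
  the contingency table (the package implements the Hubert–Arabie form;
  the test suite cross-checks it against an independent implementation).

## The synthetic-cohort generator

The original cohort was never deposited, so the generator stands in for
it. `default_cohort_spec()` mirrors the study design: $n = 928$, six
domains, 112 mixed variables apportioned to resemble a questionnaire
inventory (dichotomous clinical tests concentrated in physical
impairment, five-point ordinal scales across patient-reported domains, a
few continuous measures), domain category counts $(7,7,7,7,6,8)$, and 5%
MCAR cell missingness — under which at least 95% of rows have more than
86% complete data, matching the completeness profile of the study cohort
(the tests verify this on the generated data).

Structure is planted in two layers: each patient draws a global class
from mixing weights (default three equal classes), and each domain
derives the patient's domain category from the global class through a
*coupling* — `identity` (category = class), `noisy` (uniform relabelling
with some probability) or `independent` (no shared structure). All three
regimes ship because how domains interrelate is exactly the open question
the two approaches probe: identity coupling is the favourable regime for
two-stage recovery, independent coupling is its null.

Given the category, categorical indicators draw from
$\theta(\delta) = (1-\delta)\,\mathrm{uniform} + \delta\,\mathrm{extreme}$,
where each (variable, category) pair anchors its extreme (a point mass)
on a randomly chosen level; continuous indicators are
$N(\delta \cdot \mathrm{offset}_c,\, 1)$ with offsets a per-variable
random permutation of anchors spaced 1.5 apart and centered at zero. At
$\delta = 0$ every variable is independent of the planted structure; at
$\delta = 1$ categorical draws are deterministic. The default separation
0.85 was chosen once as a realistic "clearly present but noisy" regime —
conditional probabilities around 0.9 for anchored levels, the order of
what strong questionnaire items show — and is used unchanged by the
recovery suites.

What the generator does **not** emulate: real marginal distributions of
any clinical variable, within-class residual correlation (real items
violate local independence; the generator satisfies it exactly, so
passing recovery tests show correctness of the machinery, not robustness
to model misspecification), non-MCAR missingness, and the clinical
meaning of categories. Conclusions about the *methods* transfer;
conclusions about *low back pain* do not.

## Numerical choices and degenerate inputs

* Probability floor $10^{-6}$ (renormalized), variance floor
  $10^{-6} \times$ sample variance: prevent $-\infty$ likelihoods.
* Ties in modal assignment break toward the lowest class index; ties in
  restart retention toward the earlier restart; both deterministic.
* A constant variable gets association 0 in `loadings()` with a warning
  (its Cramér's V / correlation ratio is undefined).
* A dataset column entirely missing is permitted per-domain (the row
  posterior reduces to the class weights) but a fully missing row is
  rejected at construction.
* `n_parameters()` on an empty codebook is an error (a codebook must
  declare at least one variable), as is $K > n$.
* Reported percentages round half away from zero (219/928 → 24%).

## Problem sizes used by the test and acceptance suites

The recovery suites run on a reduced six-domain template — three
variables per domain (two 3-level nominal, one 4-level ordinal) plus one
continuous variable in each of two domains, 20 variables in all — at
$n = 1000$, $G = 3$ equal classes, $\delta = 0.85$, 3% missingness, two
restarts per class count, class counts searched to 6, and EM tolerance
$10^{-6}$. These sizes were fixed once as the smallest design in which
the planted structure is comfortably identifiable (identifiability needs
response-pattern diversity: a domain observed through only three
variables has so few distinct patterns that a 3-class model on it alone
is not identified — solutions merging two categories attain the same
likelihood, which is also why the per-domain recovery example in the test
suite uses six-variable domains). The identity-coupling two-stage suite
fixes the per-domain class counts at the planted value, mirroring a first
stage whose results are taken as given.

## Known limitations

* Ordinal items as unordered multinomials: no partial credit for
  near-miss categories; BIC comparisons with ordinal-aware software will
  differ systematically.
* No covariates on class membership, no Bayesian estimation, no
  bootstrap likelihood-ratio tests — outside the implemented methodology.
* The consensus step that picks the *preferred* model is human by design;
  the package stops at the starting model plus the reports that feed that
  judgement.
* Greedy feature grouping depends on variable order for borderline
  concordance patterns; the order is the profile's (codebook) order and
  is documented as such.
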