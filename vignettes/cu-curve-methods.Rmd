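---
title: "Clinical utility curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical utility curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cucurve)
```

## The CU curve

A risk prediction model assigns each patient an absolute risk $p_i \in
[0,1]$ of a binary outcome. For a threshold $t$, the rule "positive if
$p_i \ge t$" partitions the cohort into flagged and unflagged patients, and
the two quantities the CU curve pairs are

$$\mathrm{sensitivity}(t) = \frac{TP(t)}{n_\text{cases}}, \qquad
\mathrm{NNCOC}(t) = \frac{TP(t) + FP(t)}{TP(t)} = \frac{1}{\mathrm{PPV}(t)}.$$

NNCOC — the number needed to capture one case — is the per-case price of
the rule in flagged patients, analogous to the number needed to treat. The
CU curve is the locus of $(\mathrm{NNCOC}(t), \mathrm{sensitivity}(t))$
over all distinct risk values $t$, in descending threshold order. It uses
exactly the information behind the ROC curve (at every threshold,
$1-\text{specificity}$ here equals the ROC curve's false-positive rate; a
test asserts this threshold-by-threshold) but re-parameterises the x-axis
into an actionable, prevalence-dependent unit.

Conventions, all load-bearing:

* **Classification rule is $\ge t$**, matching the usual "absolute risk
  ≥ x %" phrasing. Strict inequality is not offered.
* **Ties cross together.** A threshold on a score cannot split equal
  scores, so the curve is indexed by *distinct* risk values, never by
  patient rank.
* **Zero-true-positive thresholds are omitted.** Above the top-ranked case
  the NNCOC is undefined (0 flagged cases); those points are dropped rather
  than plotted at infinity.
* **The zigzag is preserved.** NNCOC moves by discrete jumps in
  $(TP+FP)/TP$ and is not monotone in $t$; the implementation never sorts,
  smooths or monotonizes it.
* **Risks are proportions internally**; percent formatting happens only at
  display (tables print NNCOC to one decimal, the conventional reporting
  precision).

The summary clinicians use most is the *first* (highest-threshold) point at
100 % sensitivity: all patients below it are non-cases, so
`full_sensitivity_summary()` reports the threshold, the flagged count, the
NNCOC, and the rule-out count/fraction. `threshold_for_sensitivity()`
generalises this to any target, returning the highest threshold whose
sensitivity meets the target under the exact $\ge$ rule — note that with 3
cases a target of 0.67 is *not* met by 2/3 = 0.667, so targets should be
supplied as exact fractions when that is what is meant.

### Degenerate cohorts

A curve needs at least one case (otherwise every point is omitted and the
curve is empty — an error). A cohort with no non-cases has a well-defined
curve (specificity aside), and the all-cases limit is occasionally useful
as a sanity check, so `build_cu_curve(strict = FALSE)` permits it with
specificity `NA`; the default `strict = TRUE` rejects both single-class
cohorts, which is almost always the right behaviour on real data.

### Uncertainty

NNCOC point estimates carry no confidence intervals by default: with
desk-scale cohorts the sampling variability of the 100 %-sensitivity point
is dominated by the lowest-ranked case, and out-of-sample validation is the
better answer. For exploration, `nncoc_bootstrap_band()` offers percentile
intervals by patient-level resampling (default 2000 replicates, explicit
seed required); resamples that lose an outcome class are redrawn, at most
100 times.

## Logistic risk scoring

`fit_logistic()` is plain maximum likelihood via iteratively reweighted
least squares (tolerance $10^{-8}$ on the relative deviance change, at most
50 iterations — standard IRLS practice), with standard errors from the
inverse observed information at the optimum. Design choices:

* **No regularisation.** Separation — diverging coefficients with fitted
  risks pinned to 0/1 — is an explicit error, not something penalised away;
  detection combines boundary fitted values with a coefficient magnitude
  exceeding 10 on the log-odds scale.
* **Covariates as given.** No automatic standardisation; predicted risks
  are invariant to affine rescaling of continuous covariates anyway (a
  property test asserts agreement to $10^{-8}$).
* **Numeric columns only.** Categorical predictors must be pre-expanded to
  indicator columns by the caller; the fitter refuses non-numeric input and
  zero-variance columns.
* Every returned fit satisfies the score equations to $10^{-6}$ (asserted
  in tests), and non-convergence is flagged (`converged = FALSE`, warning)
  rather than hidden.

In-sample fitted risks feed the curve and calibration functions, as is
conventional; this is optimistic relative to external validation.

## C statistics and their comparison

`c_statistic()` uses the Mann–Whitney form (ties count one half) with
variance from the DeLong structural components. The components are computed
with midranks — algebraically identical to the $O(mn)$ pairwise definition
but $O(n \log n)$ — and the test suite verifies exact equality against an
exhaustive pair-counting oracle and against pROC. Confidence intervals are
normal-theory on the AUC scale, truncated to $[0,1]$; a percentile
bootstrap CI for a paired difference comes with `compare_auc_bootstrap()`.

Two comparison routes exist by design and are cross-validated against each
other in tests:

* **DeLong z-test** (`compare_auc_delong()`): paired mode uses the
  component covariance; unpaired mode (disjoint subgroups scored by one
  pooled model) assumes independence, i.e. zero covariance.
* **Patient-level bootstrap** (`compare_auc_bootstrap()`): both scores are
  resampled on the same patient draw; the two-sided p-value is the tail
  proportion of the difference distribution against zero,
  $\min(1,\, 2\min(P(d\le 0), P(d\ge 0)))$. Default 2000 replicates; the
  seed is a required argument.

All p-values in the package are two-sided.

## Continuous NRI and IDI

Both indices compare an old and a new model on the same patients and are
implemented from their standard category-free definitions:

$$\mathrm{NRI} = [P(\uparrow\mid e) - P(\downarrow\mid e)] +
[P(\downarrow\mid ne) - P(\uparrow\mid ne)]$$

with "up/down" meaning *any* change in predicted risk (no minimum-change
epsilon; exact ties count in neither direction), and

$$\mathrm{IDI} = (\bar p_{new,e} - \bar p_{old,e}) -
(\bar p_{new,ne} - \bar p_{old,ne}),$$

the change in discrimination slope. Standard errors are asymptotic: the
binomial-style form for the NRI proportions, and per-class sample variances
of the individual risk changes for the IDI. Bootstrap SEs would be a
reasonable alternative at very small n; the asymptotic choice is documented
rather than claimed superior. Degenerate zero-SE cases (e.g. uniform risk
shifts within each class) return `p = NA` with a warning — except the exact
null of identical models, where `p = 1`. Antisymmetry under swapping
old/new is exact and tested, and a 200-replicate null simulation (noise
covariate refit on each replicate) checks that the NRI test's type-I error
stays within [0.02, 0.10] at $\alpha = 0.05$.

## Hosmer–Lemeshow calibration

Patients are ranked by predicted risk and cut into `n_groups` (default 10,
the convention) quantile groups using right-closed intervals, so patients
sharing a boundary risk value stay together in the lower group; heavy ties
can merge groups, and the degrees of freedom follow the *realised* group
count minus 2. The statistic sums $(O-E)^2/E$ over both the event and
non-event margins. A group with zero expected events (or non-events) makes
the statistic undefined and raises an error advising fewer groups. Tie
handling in HL grouping differs across published implementations, so exact
reproduction of any particular software's p-value on tied data is not
claimed.

## Synthetic cohorts: what they emulate and what they do not

`generate_logistic_cohort()` draws covariates per spec (normal or
Bernoulli), computes true risks through a stated logistic model, and draws
outcomes as Bernoulli(true risk). The defaults emulate the *shape* of a
referred-for-angiography cohort: n = 303, two continuous covariates, a
binary sex indicator with prevalence 0.68 carrying a log-odds of 1.98, and
an intercept of −1.55 chosen once so that outcome prevalence lands near
139/303 ≈ 0.46. The smaller biomarker-style example (37 patients, 15
cases) is represented in tests by rank-constructed cohorts in which the
printed flagged/case counts are imposed directly.

`generate_binormal_cohort()` draws case and control scores from two
normals and squashes them through the inverse logit, which preserves every
rank (hence the AUC exactly — property-tested) while making scores read as
risks; the closed-form binormal AUC
$\Phi\!\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2}\big)$ travels along
as metadata.

All generators take an explicit seed, scope it with `withr::with_seed`
(the caller's RNG state is never touched), and are bit-for-bit reproducible.

What passing tests on these cohorts show: the estimators are correct on
data that satisfy the logistic / binormal assumptions exactly. What they do
not show: behaviour under model misspecification, correlated or missing
covariates, measurement error, or case-control sampling — real cohorts have
all of these, and the in-sample evaluation here is optimistic by
construction.

## Problem sizes and numerical tolerances

The test suite runs at desk scale by choice: exact-equality oracle checks
use cohorts of 5–50 patients (where exhaustive enumeration is the
reference); parameter-recovery uses 100 replicates at n = 10 000;
null-calibration checks use 300 replicates (Hosmer–Lemeshow, n = 1000) and
200 replicates (unpaired DeLong, 60 + 60 per arm); DeLong-variance
validation uses 500 replicates at 1000 + 1000. Identities expected to hold
in exact arithmetic (NNCOC · PPV = 1, curve/ROC agreement) are asserted at
$10^{-12}$; stochastic recoveries at the tolerances stated in the tests
(e.g. AUC within 0.02 of the binormal closed form at 5000 + 5000).

## Known limitations

* No decision-analytic weighting: net benefit, weighted NRI and
  relative-utility curves are out of scope by design — the threshold
  weighting belongs to the clinician, and the CU curve presents the raw
  trade-off instead.
* No survival/time-to-event outcomes, variable selection, interactions, or
  penalised fits.
* The subgroup workflow fits one pooled model by default and evaluates it
  per group; `--fit-per-group` refits within groups, but small subgroups
  will overfit and the package does not guard against that beyond the
  separation error.
* CSV is the only interchange format.
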