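---
title: "Methods: matched case-control comorbidity analysis with lift-ranked rule mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched case-control comorbidity analysis with lift-ranked rule mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidARM)
```

## The design

comorbidARM implements the analysis pattern of registry-based comorbidity
studies of a rare index disorder — here borderline personality disorder
(BPD, ICD-9-CM 301.83) — in claims-like diagnosis records:

1. **Incident case selection.** A person is a case when their *first-ever*
   index-code record falls inside the enrollment window; that date becomes
   their index date. Persons whose first record predates the window are
   excluded, and any index-code carrier is barred from the control pool.
2. **1:4 exact matching.** Each case receives four controls of identical sex
   and identical age (completed years at the case's index date), drawn
   uniformly at random without replacement across the cohort. Exact matching
   makes the control marginals equal the case marginals, so the demographic
   comparison table is flat by construction (all P ≈ 1).
3. **Comorbidity windowing.** A member's comorbidity set is the union of
   diagnosis categories recorded within ±3 years of the index date (closed
   window; controls inherit their matched case's index date, the standard
   matched-design convention).
4. **2×2 odds ratios.** For each category the case-vs-control odds ratio is
   the cross-product OR = (ad)/(bc) with a Wald interval
   exp(ln OR ± z·sqrt(1/a + 1/b + 1/c + 1/d)), z = 1.959964 at the 95%
   level. For a single binary exposure this coincides with the exponentiated
   univariable logistic-regression coefficient (asserted numerically in the
   tests). The same estimator, applied to the female-vs-male split *within*
   cases, gives the sex-stratified columns of the category tables.
5. **Rule mining.** Each member contributes one *transaction*: the index
   item (cases only) plus their psychiatric comorbidity categories. Rules
   X → Y over disjoint item sets are scored by
   support s = P(X ∪ Y), confidence c = P(Y | X), and
   lift = c / s(Y) = P(X, Y) / (P(X) P(Y)). Mining runs in the *lift-only*
   regime: minimum support and confidence are zero, every rule with
   lift strictly above 1 is admissible, output is ranked by lift and
   truncated to the top k (default 10 000), and the reported family is
   restricted to antecedent {BPD} with consequent sizes 2–3.
6. **Validation.** The cohort is split person-wise 2/3 : 1/3, stratified by
   group; rules discovered on the training set are re-evaluated on the
   held-out third, including a per-rule case-control OR of the consequent
   pattern.
7. **Matched bootstrap.** Each of B = 1000 replicates resamples the cases
   with replacement, re-matches four controls per drawn case by exact
   age/sex from the pool, rebuilds the transactions and recomputes every
   rule's metrics; per-rule means and percentile confidence intervals are
   reported across replicates.

## Numerical conventions

* **Age** is completed years under a 365.25-day-year convention
  (`floor(days / 365.25)`), used consistently by the generator, the matcher
  and the demographics table, which avoids calendar edge cases.
* **Windows** are closed and measured in whole days: w years =
  `round(w * 365.25)` days, so a record dated exactly w years away counts.
* **Zero cells** make an OR undefined; it is reported as `NA` and rendered
  `"--"`, matching how such entries appear in study tables. The
  Haldane-Anscombe +0.5 correction is available behind a flag but off by
  default.
* **Quantiles** (median/IQR) use linear interpolation (R type 7); bootstrap
  percentile intervals use order statistics (inverse-ECDF, type-1) so they
  are exactly elements of the replicate vector.
* **Tie-breaking** in rule ranking is deterministic: lift, then support,
  then confidence (all descending), then the rule label — the published
  ordering is undefined at ties and determinism is required for testing.
* **Split sizes**: the training set holds `round(f·n)` members in total of
  which `round(f·n_cases)` are cases, controls being the remainder. For
  292/1168 at f = 2/3 this gives 195/778 and 97/390 — the only partition
  under which the published per-rule odds ratios and intervals are
  internally consistent (e.g. a test-set rule with counts 42/1 yields
  OR 297 and CI 37.9–684 only with 390 test controls).
* **Report formatting**: percentages to one decimal, ORs to three
  significant figures (integers above 100).

## The synthetic claims generator

The registry that motivates this design is access-restricted, so the package
ships a generator whose outputs have *known* statistical structure;
every downstream stage is tested against that ground truth.

Each person gets a sex (65% female), an integer age drawn by
piecewise-linear inverse-CDF interpolation through quantile anchors chosen
so that the floored ages reproduce the study demographics (median 25,
IQR 21–33; 12.7% / 77.4% / 9.9% in the 0–19 / 20–39 / 40–59 bands), an
index or pseudo-index date uniform in the 2003–2006 enrollment window, and a
birth date consistent with the age at that date. Category membership is
sampled per person from a logistic model

&nbsp;&nbsp;logit P(g) = logit(p0_g) + log(OR_g) · case [+ pairwise couplings],

so the population case-vs-non-case odds ratio for category g *is* the
configured `category_target_or[g]` — exactly the quantity the downstream
estimators recover. Optional auto-logistic couplings (earlier categories
feeding later ones) induce inter-category dependence; they shift the
marginal prevalences and ORs and are off by default. Each membership is
emitted as one concrete ICD-9-CM code drawn from a small fixed
representative list per category (category identity, not code identity,
drives the analysis; the lists are chosen so each code maps back to exactly
its intended category), dated uniformly within ±3 years of the person's own
(pseudo-)index date. A `missing_fraction` flag blanks fields completely at
random to exercise complete-case filtering.

Default prevalences and target ORs follow the emulated study's control-arm
rates and printed estimates (e.g. depressive disorder 2.05% / OR 220,
anxiety 6.34% / OR 13.2). Categories whose control-arm rate is printed as
zero have no defined OR; they carry small stand-in rates (0.05–0.2%) with
ORs back-calculated to reproduce the printed case-arm rates. The default
index prevalence (1.5% at n = 20 000) is far above the registry's true
incidence; it is chosen so a package-scale run yields a few hundred cases
with an ample matching pool, which preserves every structural property the
pipeline exercises.

### What the generator does and does not emulate

It emulates the *statistical contract* the analysis depends on: a rare
index disorder, configurable category prevalences and case-vs-non-case odds
ratios, the demographic structure, missingness, and dated codes. It does
not model visit dynamics, utilisation, reimbursement, code granularity
beyond representative codes, secular trends, or age/sex-dependent
comorbidity rates. Passing tests therefore demonstrate that the pipeline
recovers known structure under clean conditions — not that any particular
clinical finding generalises.

### Windowing attenuation — a deliberate emulation artifact

Controls' comorbidity windows are anchored at the matched case's index date,
while the generator dates a non-case's comorbidities around their own
pseudo-index date. Since the two dates can differ by up to the enrollment
span (4 years), part of a control's comorbidity mass falls outside the ±3
year window: with uniform dates the expected retention is
E[(6 − |δ|)/6] ≈ 0.78. Cases are unaffected (their records centre on their
own index date), so end-to-end cohort ORs exceed the generator targets by
roughly the control-odds attenuation factor. This mirrors a real ambiguity
of matched claims designs (what "enrollment" means for a control is a
convention) rather than a bug. Where a test or script needs the generator
target to *be* the cohort parameter — parameter recovery, bootstrap
coverage — transactions are anchored at each member's own pseudo-index date
(`anchor = "own_index"`), which the API exposes explicitly.

## Bootstrap interval semantics

The replicate-level percentile interval (2.5/97.5 order statistics) is the
primary CI: it reflects the resampling distribution of each metric and its
width does *not* shrink as B grows — it converges. What shrinks ~1/√B is
the Monte-Carlo standard error of the reported *mean* metric, which the
summary also carries (`*_se` columns); the very narrow intervals published
for mean bootstrap metrics in this literature are on that SE-of-mean scale.
Replicates in which a rule's OR is undefined (zero cell) are excluded from
the OR mean and interval, with `n_defined_or` reporting the remainder — a
rule no control ever satisfies is printed `"--"`. A `resample_cases = FALSE`
diagnostic mode disables case resampling so that a forced-pool single
replicate reproduces the point evaluation exactly; it exists for
verification, not inference.

Within a replicate a drawn case's controls are sampled without replacement;
across cases and replicates the pool is reused (sampling with replacement at
the run level). Re-matching per replicate requires every case (sex, age)
stratum to hold at least `ratio` pool members; the `"relax"` policy widens a
thin stratum to ±1 year and is logged, the default is to fail loudly.

## Null behaviour of lift ranking

Under a null configuration (all category ORs = 1) the *true* lift of every
index rule is 1, but empirical lifts scatter around 1, so some mined rules
will exceed the strict lift > 1 threshold by chance at any sample size —
zero-support-threshold mining has no built-in error control. The package's
tests assert the true property (null lifts stay in a narrow noise band far
below the planted-signal regime, roughly 4–5 with the default
configuration); consumers ranking rules on real data should read lift
magnitudes, and the bootstrap intervals, rather than the bare lift > 1 cut.
Note also that lift in a 1:4 matched case-control transaction set is capped
at n/n_cases = 5 for index-antecedent rules; the strongest rules sit at that
ceiling, as the published tables' 4.99/5.02 values illustrate.

## Problem sizes used by the shipped checks

The test-suite populations are 1 500–30 000 persons (one 200 000-person
generation for odds-ratio recovery at Monte-Carlo precision), the oracle
comparison runs 100 random instances of ≤ 8 items × ≤ 200 transactions
against exhaustive enumeration, and the bootstrap coverage study runs 50
independent 4 000-person worlds at B = 200. These sizes give stable
verdicts for every property tested while keeping the default suite quick to
run; all of them are package choices and can be scaled up by the user.

## Known limitations

* Unconditional (unmatched) OR estimation is used throughout, as in the
  emulated study; no conditional logistic or matched-pair estimator.
* Only univariable estimates: no adjustment, no multiple-testing control.
* The psychiatric code groupings are conventional stand-ins loaded from a
  data file; substitute your own mapping for real analyses.
* The miner is level-wise enumeration bounded by rule size (≤ 4 items) and
  an itemset budget — appropriate for curated category universes (~13
  items), not for open-ended code-level mining.
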