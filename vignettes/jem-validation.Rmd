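---
title: "Building and validating job-exposure matrices from cohort self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating job-exposure matrices from cohort self-reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jembuild)
library(dplyr)
```

## The problem

A job-exposure matrix (JEM) assigns occupational exposure estimates to
*occupational groups* rather than individuals, so that exposure can be
imputed in any dataset that records only a job title and a sector of
activity. jembuild implements the construction and internal validation of
such a matrix from individual-level cohort data in which workers carry

* a 4-character occupation code from a three-level nested classification
  (1-, 2- and 4-character levels, PCS-2003 style),
* an activity-sector code of 1–5 characters from a five-level nested
  classification (NAF-2008/NACE style), recorded at whatever depth is
  available for that worker, and
* self-reported responses to a battery of exposure questions on mixed
  scales.

The occupational group is the cross of the two codes (the *standard*
keying); an occupation-only (*simplified*) and an
occupation × sector × establishment-stratum (*alternative*) keying are also
supported, the stratum crossing public/private with establishment size
below / at-or-above 200 employees.

## The group-based frequency method

For each exposure the pipeline in `build_jem()` is:

1. **Dichotomize** the raw response (see below), and drop records missing
   that one exposure (complete case per exposure — a record missing one
   exposure still contributes to all others).
2. **Exclude small groups**: groups with ≤ 10 complete-case members are
   removed from that exposure's analysis. Sizes are counted on the full
   dataset, before splitting, because the exclusion is a property of the
   analysis dataset, not of a split.
3. **Split** the cohort once into a 70% learning and 30% test set by
   simple random sampling (no stratification), shared by all exposures.
4. **Estimate** each group's exposure frequency — the fraction of its
   learning-sample members reporting the exposure. This fraction *is* the
   JEM's exposure assessment for the group.
5. **Scan** dichotomization thresholds over the grid 0, 0.05, …, 1.00:
   test individuals are predicted exposed iff their group's frequency
   strictly exceeds the threshold, and Cohen's κ, F1, sensitivity and
   specificity are computed against self-report at each grid point.
6. **Select** the cut-off with the highest F1; F1 ties are broken by the
   highest specificity (minimizing false positives), residual ties by the
   highest threshold so that selection is deterministic.
7. **Report** performance: AUC on the *continuous* group frequencies
   (independent of the cut-off) plus κ/F1/sensitivity/specificity at the
   selected cut-off; then recompute the frequencies on the full dataset
   with the selected cut-off carried over, giving the published-style JEM.

### Dichotomization rules

| scale | range | exposed when |
|---|---|---|
| binary | 0/1 | reported |
| 4-point Likert | 1–4 | ≥ 3 ("often" or "always or nearly always") |
| physical-effort level | 0–3 | = 3 (heavy efforts only) |
| Borg RPE | 6–20 | ≥ 13 (intense physical effort) |
| effort–reward imbalance | ratio | ≥ 1.5 |

The ERI ratio is computed from Siegrist's short form as
sum(3 effort items) / (sum(7 reward items) × 3/7); the 3/7 factor corrects
the unequal item counts so identical per-item scoring balances at 1.
Cohorts that ship a precomputed score column should use it directly —
`eri_score()` is a convenience for raw items. On 1–4 items the formula's
range is 0.25–4; published questionnaires sometimes state a minimum of
0.33, reflecting slightly different item coding, but the ≥ 1.5 cut-off is
unaffected.

### Performance measures

All measures are implemented from first principles in `R/metrics.R` and
checked in the test suite against brute-force oracles and an established
ROC implementation:

* **Cohen's κ** = (p~o~ − p~e~)/(1 − p~e~), with interpretation bands
  poor (0–0.20), fair (0.21–0.40), moderate (0.41–0.60), good (0.61–0.80),
  excellent (0.81–1), applied at the printed two-decimal convention.
* **AUC** via the tie-corrected Mann–Whitney statistic (midranks).
  This choice is load-bearing: all members of a group share one frequency,
  so the score distribution is massively tied, and the midrank convention
  equals the trapezoidal area under the empirical ROC curve.
* **Sensitivity, specificity, F1** from the 2×2 table, with a
  zero-denominator metric defined as 0. The definition matters at the grid
  extremes: threshold 1.0 predicts nobody exposed, and F1 = 0 there
  guarantees such a cut-off is never selected.

Whether the reported AUC should use continuous frequencies or binarized
assignments is genuinely open; we use continuous scores (the more common
convention, and the one that makes AUC cut-off-free) and expose the
binarized value (sensitivity + specificity)/2 as a diagnostic column.

## The machine-learning comparator harness

`compare_methods()` benchmarks the frequency method against a single
probability tree (CART), a random forest (ranger) and gradient-boosted
trees (xgboost) under identical conditions: same split, same threshold
rule, same evaluation sample.

* **Variable sets.** Codes are truncated to every informative combination
  of occupation depth {none, 1, 2, 4} × sector depth {none, 1, …, 5} —
  23 sets — dummy-encoded, with constant indicator columns dropped. Each
  learner is tuned per set and the set with the highest cross-validated
  AUC wins (ties to the smaller design).
* **Class imbalance.** Several exposures sit below 5% prevalence, so each
  class is inverse-probability weighted to carry half the total weight
  (weights N/(2n~k~), summing to N).
* **Tuning.** Hyperparameters are selected by 10-fold cross-validated AUC.
  Folds are drawn unstratified once; if a fold lacks a class — likely at
  desk-scale n with rare exposures — they are redrawn with class
  stratification. Default grids are deliberately small (tree depth
  {2,4,8,30} × min-leaf {5,20}; forest trees {200,500} × mtry {√p, p/3};
  boosting depth {2,4} × η {0.1,0.3} × rounds {100,300}) and overridable.
* **CART as a probability tree.** The single tree is fitted as an anova
  tree on the 0/1 outcome rather than a misclassification-loss tree:
  leaf predictions are then (weighted) exposed fractions, and splits are
  kept whenever they reduce impurity. This gives the method-equivalence
  limit exactly — a saturated, unweighted tree on the full-depth variable
  set reproduces the group-based frequencies — whereas a risk-gated
  classification tree refuses splits between groups whose frequencies lie
  on the same side of 0.5 and breaks that limit.
* **Uncertainty.** Per-method AUC intervals are percentile bootstrap over
  test individuals (default 500 resamples), paired across methods by
  sharing resample indices. Groups with no learning-sample member cannot
  be scored by any method; their test members are excluded from the
  comparison sample once, so every method sees the same individuals.

## The synthetic cohort generator

No individual-level healthcare-cohort data can ship with the package, so
`generate_cohort()` produces cohorts with known ground truth that emulate
the structure the method was designed for:

* **Size and codes.** 12 489 individuals, 31 occupation codes, 144
  occupation × sector pairings (the defaults), with format-valid synthetic
  codes whose nested prefixes behave like the real classifications.
* **Group-size skew.** Individuals are allocated to pairings by a
  truncated power law with exponent 1.5. This was calibrated once so the
  generated structure mirrors the situation the method faces in practice:
  a minority of groups (typically ~45%) exceed 10 members, yet those
  groups cover over 95% of individuals, and the largest group holds
  roughly a third of the cohort (as a dominant profession such as nurses
  does).
* **Exposure truth.** Per-group prevalences are drawn from
  Beta(m·c, (1−m)·c) around each exposure's marginal target m with
  concentration c = 4, then recentred by a logit-scale shift solved so the
  size-weighted mean equals m exactly. Without the recentring the realized
  marginal drifts by several points under the skewed size law; with it,
  realized prevalences track their targets to well under one point at the
  default n. Binary responses are Bernoulli draws from the group
  prevalence; ordinal and continuous responses (Likert, Borg, effort,
  ERI) are generated by inverting the dichotomization rule, so
  dichotomization recovers the generated binary truth exactly.
* **Missingness** is injected completely at random per exposure at each
  exposure's target rate (0.6–4.7%). MCAR keeps complete-case analysis
  unbiased, which is what makes the parameter-recovery tests clean.
* **Passenger realism.** Establishment type/size (public 53.7%, ≥200
  employees 67.6%, with realistic missingness), sex (80.5% female) and age
  (median 41) are generated but drive no exposure.

What the generator does **not** emulate: correlations between exposures
(the JEM treats exposures independently, so none of the validated
quantities depend on them), differential missingness, within-group
heterogeneity by unmeasured factors (hospital department, preventive
measures), and the true — unpublished — group-size distribution, for which
the power law is a stand-in. Passing tests therefore demonstrate that the
machinery recovers known structure under the stated generative model, not
that any particular real cohort satisfies that model.

`make_separable_cohort()` provides the analytic fixture: two strata of
groups at prevalences ½ ± gap/2, whose two-point score distribution has a
closed-form AUC (`two_point_auc()`); gap = 1 is the exactly separable
limit (AUC = κ = 1) and gap = 0 the uninformative one (AUC = ½).

## Numerical choices and degenerate inputs

* "Frequency exceeds the threshold" is implemented strictly (>): a group
  at exactly the cut-off is unexposed, and threshold 1.0 predicts nobody.
* The threshold grid is rounded to 10 decimals so binary comparisons are
  not poisoned by floating-point accumulation in `seq()`.
* κ with both margins degenerate (p~e~ = 1) returns `NaN`; AUC with a
  single truth class is an error (`jembuild_degenerate_truth`) because no
  ranking statement is possible.
* A retained group with no learning-sample member is unassigned: its test
  members are flagged and dropped from scans rather than scored. At
  realistic cohort sizes this cannot occur.
* Records whose codes fail to parse, or that lack a component the keying
  variant needs, are flagged ungroupable and counted, never silently
  dropped.
* Per-exposure failures inside `build_jem()`/`compare_methods()` are
  recorded in `failures` and skipped, so one degenerate exposure cannot
  abort a 24-exposure build.

## Open design points, resolved

* **The 23 variable sets.** The count is reproduced exactly by crossing
  occupation depths {none, 1, 2, 4} with sector depths {none, 1, …, 5} and
  removing the uninformative (none, none) pair: (3+1)(5+1) − 1 = 23. We
  adopt this reading; it is the only natural interpretation consistent
  with a three-level occupation and five-level sector classification.
* **Thresholds in the final JEM** are carried over from the 70/30
  validation rather than re-optimized on the full dataset, keeping the
  published cut-off attached to the performance estimates that justified
  it.
* **Sector codes of heterogeneous depth** key groups at their *declared*
  depth; records are never up-coded to a depth they did not declare. When
  applying a built JEM to new data (`assign_exposures()`), unmatched
  sector codes fall back through truncations 5 → 4 → … → 1 before being
  flagged unmatched.

## Problem sizes used in validation

The shipped tests and the acceptance script run the default 12 489-record
generator for structural and scan-law checks (a full 24-exposure build
takes a few seconds), 60 groups of 250 for Beta-prevalence recovery, 6 000
records for the separable-fixture AUC comparison, and reduced learner
grids with a single full-depth variable set for the method-equivalence
checks. These sizes were chosen so each check's Monte-Carlo error is
comfortably inside its assertion band.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(cohort_config(seed = 7))
jem <- build_jem(sim$records, seed = 42)
glance(jem)       # per-exposure AUC, cut-off, kappa, F1, spe, sen
tidy(jem)         # the JEM itself: group x exposure rows
autoplot(jem)     # dot plot of AUC and kappa per exposure
write_jem(jem, "jem.csv")

# deploy to a dataset with job codes only
assign_exposures(jem, new_workers)
```

## Known limitations

A JEM assigns group-average exposure; within-group heterogeneity becomes
non-differential misclassification at the individual level, and nothing
here mitigates that. The generator's independence and MCAR assumptions are
idealizations. The learner grids are desk-scale defaults, not an
exhaustive search. External validity — agreement with other matrices or
with health outcomes — is out of scope: this package quantifies internal
validity only.
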