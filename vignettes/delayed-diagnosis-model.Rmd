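---
title: "Estimating excess cancer mortality from lockdown-related diagnostic delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess cancer mortality from lockdown-related diagnostic delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodelay)
```

## The problem

During the first COVID-19 lockdown in France, consultations for a *new*
cancer diagnosis in the Unicancer network of comprehensive cancer centers
dropped abruptly — by about a fifth in April and May 2020 — and the missing
patients had not reappeared by the end of the year. A patient who does not
present is a patient whose diagnosis is postponed, and postponed treatment
initiation is consistently associated with poorer cancer-specific survival.
`oncodelay` packages the chain of reasoning from monthly count tables to an
expected excess-death estimate so that every link can be tested, audited
and re-parameterized.

## Model and assumptions

The quantity of interest is the expected number of additional cancer deaths
among patients whose diagnosis was delayed. The model is deliberately
minimal:

1. **Missing patients.** For each calendar month `m`, the reduction
   fraction is `f_m = (ref_m − obs_m)/ref_m`, where `ref` is the same month
   of the reference year. Months where activity *increased* contribute zero
   missing patients (clamping): only deficits are interpreted as delays,
   and a later surplus is not allowed to "repay" an earlier deficit, since
   the observed data show no compensation after the lockdown.
2. **Delay assignment.** All patients missing in month `m` are assumed to
   enter care in a single *resolution month* R (August 2020 by default), so
   their delay is `n = R − m` whole months: March → 5, …, July → 1.
   Scenario rows add `a` further months uniformly. This whole-month
   counting back from the resolution month is the only assignment that
   reproduces the published national per-month figures (42, 502, 393, 20,
   67) to within rounding.
3. **Mortality transformation.** A delay of `n` months multiplies the
   cumulative hazard of cancer death by `HR^n` (proportional hazards with a
   per-month hazard ratio), so with baseline death probability `RD` and
   survival `S = 1 − RD`,
   `RDdel = 1 − exp(ln(1 − RD)·HR^n) = 1 − S^(HR^n)`,
   and a month with `N` missing patients contributes `N·(RDdel − RD)`
   expected excess deaths. `HR^n` is used exactly as written — no
   linearized `(1 + r·n)` approximation.
4. **Extrapolation.** National estimates scale the *fractions* `f_m`, not
   raw counts, to a national baseline of monthly new diagnoses; the network
   treats roughly 21% of French cancer patients, so count-level
   extrapolation would be far noisier than fraction-level scaling.

The model makes no attempt at patient-level survival curves, stage- or
age-specific hazard ratios, or uncertainty intervals: the published inputs
provide none of the information those would need, and the output is
intended as an order-of-magnitude sensitivity analysis, not a forecast.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `rd` | 0.41 | Baseline probability of dying of cancer; 157 400 annual cancer deaths / 382 000 annual new solid-tumor diagnoses in France (2018). |
| `hr` | 1.06 | Hazard ratio per month of delay, a conservative meta-analytic estimate for frequent cancer types; sensitivity panels use 1.02 and 1.1. |
| `resolution_month` | 8 (August) | Month by which all delayed patients are assumed treated; optimistic by design, relaxed by the `extra_months` grid axis. |
| `monthly_new_cases` | 31 833 | National new diagnoses per month (annual incidence / 12, checked to 1%). |
| `extra_pct` | 0–0.25 | Additional nationwide reduction in percentage points on top of the network series; the national claims platform reported −23.3% vs the network's −6.8%, i.e. roughly 15 points deeper. |
| tumor table | packaged | Per-tumor annual incidence/deaths (2018) and HR (1.08 breast, 1.06 others) for the five-tumor comparison. |

The observed −23.3% national reduction is carried as an external constant
with a provenance note in the constants file; it is an input, never
recomputed.

## Numerical choices

* All arithmetic is floating point; rounding to whole deaths is
  display-only. The reduction fractions are rounded to three decimals
  (their published precision) before national scaling in the reporting
  pipeline, so that the pipeline reproduces the published tables' own
  arithmetic; `fraction_digits = Inf` disables this.
* `RDdel` is evaluated with `expm1`/`log1p` for accuracy at small rates,
  and returns `RD` *exactly* when `n = 0` or `HR = 1`.
* Scenario cells with `f_m + p ≤ 0` (net increase) contribute zero excess
  deaths, consistent with clamping; `f_m + p ≥ 1` is rejected as a
  configuration error naming the offending month.
* The chi-square comparison is Pearson's without continuity correction —
  the counts it is applied to are in the thousands. The rank-sum test uses
  exact enumeration up to a combined sample size of 12 without ties (the
  published comparison is 5 vs 12 centers, just above the threshold) and a
  continuity-corrected normal approximation with midranks and tie-corrected
  variance otherwise. Enumerating all 6+6 assignments shows the corrected
  approximation stays within 0.016 of the exact p-value, whereas dropping
  the correction allows gaps near 0.07.
* A table where every value is identical in both rank-sum groups yields
  p = 1 by convention, with a warning rather than an error.

## Published-table inconsistencies the package preserves

The packaged fixture mirrors the published tables as printed, including
their internal contradictions; reconciling them silently would misrepresent
the source.

* The 17 per-center rows are each internally consistent (row sums match
  their printed totals and ratios) but sum to about 3–4% less than the
  printed network totals row (45 649 vs 47 159 in 2019). Both series are
  shipped; network-level statistics use the totals row.
* Previously diagnosed patients were reported as +4.5% although the
  printed counts (46 802 vs 44 938) give +4.15%; the counts are stored.
* Two breast March–July count pairs circulate (10 525/8 428 in the text,
  10 115/8 194 in the five-tumor table); both are stored, and the
  five-tumor comparison uses the table pair.
* The published network-level per-month excess deaths (9, 83, 64, 4, 14;
  total 174) are not reproducible from the stated formula under any
  consistent delay assignment — the assignment that matches the national
  figures yields ≈ (9, 105, 82, 4, 15). The package reports its own values.
* The published tumor-specific lung value (14) exceeds anything obtainable
  from RD = 0.68, HR = 1.06 under the documented proportional monthly
  weighting (≈ 7); per-tumor monthly profiles were likely used upstream but
  are not published. The package documents the discrepancy and reports its
  computed value.
* The published nationwide "18 304 delayed diagnoses" slightly exceeds
  31 833 × Σf_m ≈ 18 113; the scaling convention behind the published
  number is unstated, and the package reports the reproducible one.

## The synthetic-data generator

`generator_config()`/`generate_cohort()` emulate the statistical structure
the analysis assumes: per-center monthly counts drawn as Poisson around a
baseline mean with ~4%/year growth, and a lockdown dip profile
(March–July depths 0.014, 0.206, 0.218, 0.018, 0.113 by default) applied in
the dip year. Two semantics matter:

* **Dip reference.** The dip is defined against the *previous year's*
  same-month expectation — in dip months the dip-year mean is the reference
  mean times `(1 − d_m·modifier)` — because that is how the study measures
  reductions (raw 2020 vs 2019 counts). `monthly_reduction()` therefore
  recovers `d_m` exactly in expectation.
* **Stratum modifiers.** Dip depths are multiplied by sex- and
  stage-specific modifiers (deeper for women and nonmetastatic disease,
  matching the observed pattern), normalized so their share-weighted mean
  is 1: the stratum structure redistributes the dip without changing the
  network-level depth. Modifiers act on the dip, not the baseline, because
  the observations concern differential *reductions*, not differential
  incidence.

Counts are integers under Poisson noise; `noise = "none"` returns the
real-valued expectation surface, which is what makes "zero bias exactly"
testable for the estimator. Reproducibility follows a documented
stream-splitting rule: center `i` draws its whole stream after seeding with
`seed + i`, so per-center output is invariant to the number of centers.

What the generator does *not* emulate: within-month reporting artifacts,
overdispersion beyond Poisson (no information on it exists in the source
tables), center-size heterogeneity, tumor-specific dip profiles, and any
infection-dynamics feedback. Passing recovery tests therefore show that the
estimator chain is consistent under the stated sampling model — not that
real hospital data satisfy that model.

## Validation strategy and problem sizes

The test suite checks each published descriptive statistic exactly (window
totals, 3 862 missing patients), the model's closed form against an
independent survival-power form and a 10⁵-draw Bernoulli Monte-Carlo,
scenario-grid cells against the published values at 1.5% relative
tolerance (the published grid was computed from percentages rounded to one
decimal, which accounts for drifts up to ~0.5%), and the five-tumor
comparison at 5%. Parameter recovery uses 200 replicates of the default
17-center generator (each dip-month estimate within 3 Monte-Carlo standard
errors of its true depth) and 150 replicates for the end-to-end
expectation check; the end-to-end comparison allows, besides 3 replicate
SEs, a 1% margin for the expected inflation of clamped deficits in
low-dip months (`E[max(ref − obs, 0)] > E[ref − obs]` when the dip is small
relative to Poisson noise — for the March depth of 1.4% this inflation is
about +15% of that month's small contribution). A consistency-of-the-ratio
study at baselines 50/500/5000 confirms the estimator's bias shrinks as
counts grow.

## Limitations

The estimates inherit every assumption above: a single resolution month, a
uniform (or five-tumor) hazard ratio, proportional monthly weighting for
tumors, no stage/age adjustment, and no uncertainty quantification. They
should be read as scenario arithmetic on published aggregates — useful for
sensitivity reasoning and for auditing the published figures, not as a
projection of realized mortality.
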