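---
title: "Methods: rule-based identification, grading and costing of treatment-related pneumonitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based identification, grading and costing of treatment-related pneumonitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotrace)
```

`pneumotrace` models the informatics workflow a cancer centre uses to
quantify immune-checkpoint-inhibitor (ICI) and radiotherapy (RT)
pneumonitis from its data warehouse: keyword screening of CT report text,
structured-treatment filtering, temporal episode deduplication, look-back
attribution, CTCAE v5.0 severity grading with dual-rater concordance,
16-week resource-utilisation extraction, and a weighted unit-cost model.
This vignette records the scientific and numerical choices behind each
stage, what the synthetic-data generator does and does not emulate, and the
package's known limitations.

## The identification cascade

### Matching semantics

Free text is normalised by lower-casing, collapsing every non-alphanumeric
run to a single space, and trimming; phrases are normalised the same way
and matched by plain substring search. This mirrors the `LIKE '%term%'`
semantics of a SQL screening query: case-insensitive, punctuation-tolerant
("ground-glass" matches "ground glass"), no stemming, and deliberately no
word-boundary enforcement — "pneumonia" matches inside "pneumonias", while
"pneumonitis" does not match "pneumonia". We kept these semantics rather
than a linguistically smarter matcher because the artifact models a
warehouse query, and because its failure modes (negated mentions, infective
mimics) are themselves part of what the pipeline must expose.

### Stage-2 scope

Flag terms are usually planted in the *request* section by the referring
clinician ("?pneumonitis"), so stage 2 — the filter phrases describing
actual radiological findings — is evaluated on the report body only. The
underlying screening practice motivates but does not mandate this
restriction, so it is configurable (`term_config(stage2_scope = "all")`);
body-only is the default because it is the reading that makes the two
stages do different work.

### Deduplication

Six months is encoded as 183 days. Per patient, reports are sorted by scan
date with a stable secondary sort on report id (the tie-break for same-day
scans, which is logged); the earliest report is kept and every report
within 183 days *of the last kept report* is suppressed, so a chain of
follow-up scans at 0, 150 and 300 days yields episodes at 0 and 300. The
greedy earliest-first rule is deterministic and idempotent, and is tested
against an independent interval-suppression oracle on random date sets.

## Attribution

Pneumonitis is attributed to ICI if any listed drug was administered in
`[d − 91, d)` and to RT if a qualifying course started in `[d − 365, d)`,
where `d` is the diagnosis date — the symptom-onset date when the case
record carries one, else the index scan date, honouring chart-review
practice of back-dating to first symptoms. Three months is encoded as 91
days and twelve as 365 (day arithmetic, not calendar months; both window
lengths are configurable). Intervals are half-open with treatment strictly
before diagnosis, so a same-day administration never attributes. Episodes
matching neither window are routed to an exclusions output rather than
silently dropped.

## Grading and concordance

Structured severity flags map to CTCAE v5.0 as a dominance cascade:
death → 5, life-threatening/intubation → 4, severe symptoms with oxygen or
admission indicated → 3, symptomatic (medical intervention) → 2, else 1.
The grade-3 criterion deliberately collapses CTCAE's oxygen-titration
detail into flags recoverable from structured EHR fields, because grades
inferred from documentation — not pulmonary function thresholds — are what
the workflow can observe. Missing flags count as `FALSE`; the mapping is
total and tested against exhaustive enumeration of all 16 flag
combinations.

Krippendorff's alpha is computed from the coincidence matrix,
`alpha = 1 − D_o/D_e`, with items rated by fewer than two raters excluded
and missing ratings allowed. The default difference metric is **interval**
on the grade integers: adjacent-grade disagreement (the common pattern in
dual clinical review) is penalised less than distant disagreement. Nominal
and ordinal metrics are selectable since toolkits differ and reported
alphas rarely state the metric. When every pairable value is identical,
expected disagreement is zero and alpha is returned as 1 by convention,
with a logged message. The implementation is checked against a brute-force
pairwise-disagreement oracle, exhaustively over every two-rater annotation
set with up to three items on three grades and on randomised multi-rater
sets with missing data.

## Resource utilisation

The utilisation window is 16 weeks = 112 days, half-open and including the
diagnosis day: events in `[d, d + 112)` count. Admissions *starting* inside
the window contribute their full recorded nights (a stay straddling the
window edge is not clipped — the admission is a consequence of the case).
Work-up flags (respiratory referral, BAL, PFT) are recorded with
days-to-event and no window cut-off, since these investigations routinely
occur beyond 16 weeks.

The severity contrast uses Welch's unequal-variance *t*-test on follow-up
clinic counts, grade 2–4 minus grade 1. Welch is the safer reading of an
unspecified "unpaired t-test" and agrees with the pooled test exactly when
variances and group sizes are equal. Grade-5 cases are excluded from this
contrast — death truncates follow-up — but remain in admission statistics.
Identical strata short-circuit to difference 0, p = 1 rather than erroring
on degenerate variance.

## The cost model

Each of the ten resource lines contributes `weight × unit_cost`; weights
are expected uses per symptomatic case and may be products
(`"10.5*0.39"` = expected nights × admission probability), parsed from the
cost-table CSV. Two conventions matter numerically:

* **Rounding.** Currency display uses round-half-up at 2 dp
  (`round_half_up()`, with a relative-epsilon nudge so that binary
  representation of values like 567.385 cannot flip a tie downward); all
  aggregation uses unrounded values. The cohort total must be
  `unrounded per-case sum × n_cases` — rounding the per-case figure first
  produces a different total, and the tests pin this distinction.
* **The admission factors.** The admission probabilities are 0.39
  (hospital) and 0.07 (critical care), matching the observed 39% / 7%
  admission shares and every per-line total. Printed renditions of this
  table exist with the two factors transposed; the shipped
  `nhs_costs_2019_20.csv` carries the assignment consistent with the line
  totals, and this discrepancy is flagged here and in `?nhs_cost_table`
  rather than silently corrected at parse time.

The immunosuppressive-rescue unit cost is itself derivable (a 3,500 mg
infliximab course at £377 per 100 mg), and `drug_course_cost()` recomputes
it as a validation check. `cost_sensitivity()` recomputes per-case cost
under per-line multiplicative/additive perturbations; cost is linear in
every weight and unit cost, so scenario effects are exact single-line
arithmetic, which the tests exploit.

## The synthetic EHR generator

The generator emulates the statistical structure the pipeline must
survive, with ground-truth labels for every patient:

* **Prevalence and mix.** 5% of patients develop pneumonitis (the study
  population denominator for all-cause cases is not observable, so this is
  a package choice giving realistic absolute case counts at
  n = 5,000), split ICI : RT : mixed = 85 : 44 : 10 among cases; severity
  mass (109, 107, 15, 4, 13)/248 over grades 1–5.
* **Onset laws.** Truncated log-normals: ICI mean 4.5 months on range
  4 days–21 months with both parameters solved so 48% of cases present
  within 3 months (the right-skew self-check); RT mean 3.6 months on
  8 days–8 months with `sdlog` fixed at 0.9. Months convert to days at
  30.44 throughout. The true onset shape is unknown — only mean and range
  are matched; the log-normal is a skew-consistent choice, not a claim.
* **Label consistency.** ICI cases receive a 21-day administration cycle
  ending 1–21 days before diagnosis (always inside the 91-day window) and
  no RT; RT cases the mirror image; mixed cases satisfy both windows. The
  attribution confusion matrix on distractor-free synthetic data is
  therefore exactly diagonal, and the tests require it.
* **Resource events.** Bernoulli usage at the configured per-resource
  probabilities among symptomatic cases; clinic-visit counts are Poisson
  with means 4.40 (grade 1) and 6.61 (grade 2–4), placing the expected
  strata difference at 2.21 visits; admission nights are Poisson 10.5
  clipped to 1–43 (critical care 6.5, 1–20). Re-challenge affects 34.6% of
  ICI cases with a truncated log-normal hold-to-restart gap, mean 73 days
  on 11–275.
* **Distractors.** At the configured rate, non-case patients carry
  query-only requests (caught by stage 2), untreated term matches (caught
  by the treatment filter), or — for treated patients — negated mentions
  and infective-pneumonia mimics, which *no* keyword cascade can reject.
  With distractors off, identification recovers ground truth exactly
  (precision = recall = 1); with negated mentions on, recall stays 1 while
  precision drops, which is why the analysis workflow includes a
  manual-validation stand-in driven by the generator's labels.

What passing tests show — and what they do not: parameter recovery within
3 binomial SE at n = 5,000 demonstrates the pipeline is an unbiased reader
of data *with this structure*. Real radiology prose has vocabulary drift,
hedging and negation far richer than the template bank; real treatment
histories have gaps, transfers and out-of-centre events. Synthetic recall
of 1.0 is a property of the generator's guarantee that every true case's
report embeds cascade-visible terms, not a claim about clinical recall.

## Problem sizes and determinism

All randomness flows from a single configuration seed; a fixed seed gives
byte-identical streams, and the pipeline itself is deterministic. The test
suite works at n = 150–2,000 patients for structural properties, 10^5
draws for distribution calibration, and one end-to-end parameter-recovery
run at n = 5,000 — sizes chosen so the full suite documents the study-scale
behaviour while remaining quick to run. The analysis workflow under
`analysis/` uses n = 5,000 with seed 1.

## Known limitations

* No negation or uncertainty handling in the cascade (by design; it models
  a SQL screen). Precision on real data depends on manual validation.
* Demographics are sampled independently of outcome and of each other; no
  joint distribution is claimed.
* Recurrent episodes after re-challenge are not simulated, although the
  deduplication logic supports multi-episode patients and is tested on
  random multi-episode date sets.
* Whether original screening evaluated stage-2 terms on the body only, and
  which alpha metric a given toolkit applies, are unknowable from
  published descriptions; both are configurable and defaulted to the
  reading defended above.
* The cost model excludes antibiotics, steroids, co-trimoxazole and
  pathology/microbiology, prices only CT thorax imaging, and assumes one
  initial plus one follow-up respiratory appointment per referred case —
  a conservative floor, which is why `cost_sensitivity()` exists.
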