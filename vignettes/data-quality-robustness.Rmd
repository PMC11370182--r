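---
title: "Measuring the data-quality robustness of computable phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the data-quality robustness of computable phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqpheno)
library(dplyr)
```

## The problem

Rule-based ("computable") phenotypes classify patients as cases of a
condition from structured EHR data: lists of ICD-10 diagnosis codes, RxNorm
medication codes and LOINC laboratory codes, combined with count, time-window
and value constraints into care pathways. Different published definitions of
the *same* condition — here type-2 diabetes (T2D) — identify visibly
different denominator populations from the same records, and every
definition's denominator erodes when the underlying data are incomplete,
inaccurate or late.

`dqpheno` turns this into a controlled experiment. It supplies

1. a tabular cohort model (demographics plus DX/RX/LAB event streams),
2. a calibrated synthetic cohort generator,
3. a declarative phenotype language with five shipped T2D definitions
   (CCW, DDC, SUPREME-DM, eMERGE, JHU),
4. seeded, nestable perturbation operators for the three data-quality
   dimensions, and
5. experiment runners producing retention curves, data-type strata,
   31-region overlap partitions, and Charlson comorbidity summaries.

Because no real patient-level data can ship with the package, the synthetic
generator is a first-class, tested component, not a fixture.

## The synthetic cohort model

### Demographics

The default profile reproduces a large mid-Atlantic academic-health-system
adult population observed over a fixed three-year window (2017-01-01 through
2019-12-31, closed on both ends): mean age 62.4 years (SD 15.4) on an 18–90
range, 51.3% female, race 52.8/31.8/5.6/9.8% white/Black/Asian/other,
ethnicity 89.9/5.3/4.8% non-Hispanic/Hispanic/other, 81.4% Maryland
residence, mean inpatient and ED visit counts 0.657 and 1.01, and a mean
Charlson comorbidity index of 2.17. "Other" sex/race/ethnicity levels stand
for missing entries and are retained, never imputed.

Two numerical choices matter here:

* **Age** is drawn from a normal truncated to [18, 90] — but truncation
  shifts the mean of a N(62.4, 15.4) down by about 1.2 years, which would
  break parameter recovery. The generator therefore solves (one-dimensional
  root find) for the latent mean whose *truncated* mean equals the target;
  only the mean is anchored, so the realised SD is slightly below 15.4.
* **Visit counts** are Poisson with the stated means. The source SDs (1.61,
  3.61) are overdispersed relative to Poisson; since visit counts feed no
  phenotype logic and only the mean is anchored, Poisson is kept for
  simplicity.

### Evidence classes

The analysis downstream depends only on *which data-type combinations can
identify a patient*, so the generator assigns each patient a latent
**evidence class**: one of the 7 non-empty subsets of {DX, RX, LAB}, or
"none". Class members receive qualifying T2D patterns strong enough to
satisfy the strictest shipped criterion for that data type:

* **DX**: ≥ 2 outpatient E11.x diagnoses on distinct days inside the
  trailing 730-day reference period (so even the diagnosis-only definition
  with the shortest reference period is satisfied);
* **RX**: ≥ 1 antihyperglycemic ingredient dispensing inside the window;
* **LAB**: ≥ 2 elevated HbA1c results (≥ 6.5%, LOINC 55454-3/4548-4) on
  distinct days.

All patients additionally receive background noise — common non-diabetes
diagnoses, non-diabetes medications, and normal-range laboratory results
(background HbA1c spans the high-normal 5.6–5.8% band but never reaches
6.5%) — at default rates of 5 DX, 3 RX and 4 LAB events per patient-year,
chosen so perturbation curves are non-degenerate. A "none"-class patient
carries no qualifying pattern of any type.

The default class probabilities give each of the 7 qualifying classes at
least 5% mass and the "none" class 22%, so about 78% of patients carry
qualifying evidence of some kind — matching the fraction of the reference
population identified by at least one phenotype. This generator emulates the
*structure* of real records, not their biology: it has no disease
progression, no correlation between comorbidity burden and T2D evidence, no
visit-level clustering of events, and uniform event dates. Passing tests
therefore demonstrate correctness of the machinery and recoverability of the
calibrated parameters, not clinical realism of any single record.

### Comorbidity calibration

Comorbidity diagnoses are drawn as independent per-category indicators over
the 17 Charlson categories (Quan ICD-10 prefixes, original weights 1/2/3/6,
shipped as a replaceable CSV). Relative category prevalences are fixed; a
single global multiplier is solved analytically so the *expected* mean
Charlson index — accounting for the severity hierarchy (complicated diabetes
over uncomplicated, metastatic over localized malignancy, severe over mild
liver disease) — equals the 2.17 target. The calibration is exact in
expectation, so the sample mean converges at the usual √n rate.

Two deliberate interactions: the two diabetes categories emit **type-1**
(E10.x) codes, so comorbidity noise never satisfies the T2D code set {E11};
and conversely, qualifying E11.x events generated for DX-class patients *do*
score in the Quan diabetes category, so a full cohort (evidence + comorbidity
events) carries a mean index somewhat above 2.17. The calibration target is
defined on comorbidity events alone, which is also what the acceptance
script measures. The source population reports a non-integer median index
(1.33), implying period-averaged scoring; only the mean is targeted here.

## The phenotype language

A **criterion** is a count threshold over a code set (prefix matching for
dot-stripped ICD-10, exact for RxNorm/LOINC), optionally on distinct days,
in a care setting, within a span of `window_days`, and — for laboratories —
with a value predicate carrying an explicit unit. A **pathway** is a
conjunction of criteria; a **definition** is a disjunction of pathways,
optionally restricted to a trailing reference period anchored at the window
end (CCW: 730 days, i.e. 2018-01-01–2019-12-31 inside the default window).

Key semantic decisions:

* **Stratum semantics.** An identified patient's data-type stratum is the
  union of data types over *satisfied* pathways — not the data types present
  in the record. This is the only reading under which a definition without a
  medication+laboratory pathway shows a structurally empty RX+LAB stratum
  while its LAB-only stratum is populated.
* **Unit discipline.** A laboratory event whose unit differs from the
  predicate's expected unit never satisfies it; there is no automatic
  conversion. This is precisely the failure mode the unit-corruption
  operator exposes.
* **Structural invariants are compile-time errors.** CCW is diagnosis-only
  with the 730-day reference period; JHU is exactly three single-criterion
  pathways, one per data type (the most inclusive definition); eMERGE admits
  no diagnosis-only, medication-only or medication+laboratory-only pathway;
  SUPREME-DM admits no medication-only pathway. The shipped YAML configs for
  DDC, SUPREME-DM and eMERGE encode pathway sets consistent with these
  constraints and with the published sources at a best-effort level; the
  engine, not the configs, is the contract, and all configs are replaceable.
* All shipped laboratory criteria use the HbA1c code set with the ≥ 6.5%
  diagnostic threshold; glucose code sets (random ≥ 200 mg/dL, fasting
  ≥ 126 mg/dL) ship in `code_sets.yaml` for custom definitions. Keeping one
  shared analyte makes the "most inclusive definition contains every other
  definition's single-data-type strata" property structural rather than
  accidental.

## Perturbation operators

Every event carries a stable integer identity; each stochastic operator
derives a per-event uniform draw from (seed, operator stream, event id).
Selection at fraction *f* is `u < f`, so selected sets are **nested** across
the increment grid under a fixed seed — identified counts are exactly, not
just on average, non-increasing along drop grids. Draws are independent
across data types and across the drop/replace/pick streams.

* `drop_events()` — incompleteness, grid 0–100% in 10% steps.
* `replace_codes()` — inaccuracy for DX/RX, same grid; a selected event
  receives a uniformly drawn *different* code from its data-type pool
  (default pool: all codes observed in the table for that type, so both
  diabetes and non-diabetes codes occur; an E08 event with pool {E08, E09}
  deterministically becomes E09).
* `scale_lab_values()` — inaccuracy for laboratories: every value is
  multiplied by (1 + δ), δ on a 2% grid from −100% to +10%. The
  multiplicative reading is the only one that makes a "percent change"
  comparable across analytes with different scales.
* `corrupt_units()` — US→UK reporting: glucose mg/dL ÷ 18.016 → mmol/L;
  HbA1c mmol/mol = 10.93 × (%) − 23.50 (the NGSP→IFCC master equation).
  Values are converted *and* relabelled, so unit-checked predicates fail.
* `shift_dates()` — timeliness: uniform forward shift by 30-day increments
  (plus 365); attrition arises from events leaving the fixed study window.
* `perturbation()/apply_perturbation()` — declarative specs, compound
  specs apply children in order; application is a pure function.

Compound axes apply one defect to all three data types simultaneously.
Compound *inaccuracy* replaces DX and RX codes at fraction *f* and pairs
that with a laboratory delta of −*f* (laboratory codes are not replaced;
their values are degraded instead) — the pairing is this package's reading
of the compounded design and is configurable.

The missingness mechanism is uniform-at-random by design; structured
(MAR/MNAR) mechanisms are out of scope.

## Experiments and their denominators

`run_grid()` re-evaluates every definition at every grid point and reports
both `retention` (count ÷ same-replicate baseline at level 0) and
`fraction_of_cohort` (count ÷ cohort size), because either denominator is a
defensible reading of "percent of the population retained". Stochastic axes
run 5 replicate seeds by default and figures show mean with a min–max band;
deterministic axes (date shifts, laboratory scaling) run once.

`overlap_partition()` computes exact counts over all 2⁵ − 1 = 31 disjoint
membership regions of the five identified sets, plus union and
all-phenotype-intersection summaries. `characteristics()` renders
Table-1-style descriptive summaries for any identified subset.

## Problem sizes and checks

The test suite exercises hand-built micro-cohorts against brute-force
oracles (exhaustive pathway × event-subset enumeration on ≤ 20 patients,
combinatorial span checks, linear-scan code matching, category-scan Charlson
scoring), property checks on generated cohorts of 400–2,000 patients (full
drop grids, structural strata zeros, nesting, level-0 identities), and
parameter recovery at n = 200,000 patients (demographics) and n = 100,000
(Charlson), each within three standard errors of the calibration targets.
These sizes keep the full suite to a few minutes while leaving Monte-Carlo
error far below the tolerances tested.

## Known limitations

* The absolute identified counts of the source study are properties of its
  private data and are not reproduction targets; only structurally forced
  results and calibrated parameters are.
* Independent comorbidity categories ignore real co-occurrence structure;
  the Charlson *mean* is the only anchored moment.
* Whether diagnosis care-setting information was available to the original
  implementations is unknown; the model carries a per-event setting because
  published source definitions use it.
* Type-1-diabetes exclusion logic beyond code-set membership is not
  modelled; neither are clinical-notes mentions (free text) of diabetes.
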