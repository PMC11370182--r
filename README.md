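# dqpheno

**Data-quality robustness analysis for computable EHR phenotypes.**

Computable phenotypes are machine-executable rule sets — ICD-10 / RxNorm /
LOINC code lists with count, time-window and value constraints, combined
into care pathways — that identify patients with a condition from
structured electronic-health-record data. Different published definitions
of the *same* condition identify different denominator populations, and
every definition degrades when records are incomplete, inaccurate or late.
`dqpheno` is for informaticists and epidemiologists who want to measure
that degradation under controlled conditions.

The package ships five type-2-diabetes definitions — CCW (CMS Chronic
Conditions Warehouse), DDC (Durham Diabetes Coalition), SUPREME-DM, eMERGE
and a Hopkins-style expert definition (JHU) — as replaceable YAML configs,
and provides:

* **`ehr_cohort()` / `read_cohort()` / `write_cohort()`** — a validated
  tabular cohort model (demographics + DX/RX/LAB event streams, CSV
  round-trip), with prefix-based ICD-10 code matching (`match_code()`).
* **`generate_cohort()`** — a calibrated synthetic generator emulating a
  ~208k-patient adult cohort (mean age 62.4, 51.3% female, 81.4% Maryland,
  mean Charlson index 2.17) with latent *evidence classes* controlling
  which data types carry qualifying diabetes patterns.
* **`compile_definition()` / `evaluate_phenotype()` /
  `data_type_stratum()`** — a declarative phenotype language whose
  evaluator reports, per identified patient, the evidence profile (the
  data-type combination that actually satisfied a pathway).
* **`drop_events()`, `replace_codes()`, `scale_lab_values()`,
  `corrupt_units()`, `shift_dates()`, `apply_perturbation()`** — seeded,
  *nested* perturbation operators: for a fixed seed the events selected at
  10% are a subset of those selected at 20%, so degradation curves are
  exactly monotone, not just on average.
* **`run_grid()`, `overlap_partition()`, `charlson_scores()`,
  `characteristics()`, `export_report()`** — experiment runners producing
  retention curves over the study grids (drops 0–100% by 10%; laboratory
  deltas −100%…+10% by 2%; date shifts 30–365 days), 31-region overlap
  partitions, Quan-mapped Charlson summaries and tidy CSV reports, with
  `autoplot()` methods for figures.

## Worked example

```r
library(dqpheno)
library(dplyr)

co <- generate_cohort(seed = 42, n = 5000)
co
#> <ehr_cohort> 5000 patients, 205012 events (90997 DX / 49166 RX / 64849 LAB),
#>   window 2017-01-01..2019-12-31

defs <- shipped_definitions()
results <- lapply(defs, function(d) evaluate_phenotype(co, d))
bind_rows(lapply(results, glance))
#>   phenotype  n_identified n_cohort fraction_identified
#> 1 CCW                2839     5000               0.568
#> 2 DDC                3900     5000               0.78
#> 3 SUPREME_DM         3529     5000               0.706
#> 4 EMERGE             2658     5000               0.532
#> 5 JHU                3900     5000               0.78
```

78% of this synthetic cohort is identified by at least one definition (the
generator's calibrated fraction of patients carrying qualifying evidence);
the diagnosis-only CCW and the corroboration-requiring eMERGE identify the
fewest patients.

Degrade the diagnosis stream and watch the definitions separate:

```r
g <- run_grid(co, defs, axis = "incompleteness",
              data_type_targets = list("DX"), seeds = 1:3)
filter(g, level %in% c(0.3, 1), replicate_seed == 1) |>
  select(phenotype, level, n_identified, baseline_n, retention)
#>    phenotype  level n_identified baseline_n retention
#>  1 CCW          0.3         1990       2839     0.701
#>  2 DDC          0.3         3650       3900     0.936
#>  3 SUPREME_DM   0.3         3260       3529     0.924
#>  4 EMERGE       0.3         2635       2658     0.991
#>  5 JHU          0.3         3855       3900     0.988
#>  6 CCW          1              0       2839     0
#>  7 DDC          1           3029       3900     0.777
#>  8 SUPREME_DM   1           1984       3529     0.562
#>  9 EMERGE       1           1984       2658     0.746
#> 10 JHU          1           3029       3900     0.777

autoplot(g)   # retention curves, mean line with min-max band per phenotype
```

At 30% diagnosis incompleteness CCW has already lost 30% of its population
while multi-data-type definitions lose 1–8%; at 100% the diagnosis-only
definition identifies nobody, and the survivors are exactly the patients
reachable through medication or laboratory pathways.

Overlap of the five identified sets, partitioned into the 31 disjoint
membership regions:

```r
ov <- overlap_partition(unname(results))
glance(ov)
#>   denominator_n union_n intersection_n fraction_any fraction_all
#> 1          5000    3900           1968         0.78        0.394
```

## Learning more

The methods vignette (`vignettes/data-quality-robustness.Rmd`) documents
the generator's model and its calibrations, the phenotype-language
semantics (stratum definition, unit discipline, structural invariants),
the perturbation design (nested per-event uniforms, grids, compound axes)
and the package's known limitations.
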