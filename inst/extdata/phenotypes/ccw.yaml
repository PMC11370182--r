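# CMS Chronic Conditions Warehouse style definition: diagnosis codes only,
# counted inside a trailing two-year reference period.
name: CCW
reference_period_days: 730
pathways:
  - name: inpatient_diagnosis
    criteria:
      - data_type: DX
        code_set: t2d_dx
        min_count: 1
        setting: inpatient
  - name: outpatient_diagnoses
    criteria:
      - data_type: DX
        code_set: t2d_dx
        min_count: 2
        distinct_days: true
        setting: outpatient
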