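# SUPREME-DM style definition: diagnosis routes (inpatient once, or twice
# on distinct days within two years), repeated elevated HbA1c, and
# combination routes; no medication-only pathway.
name: SUPREME_DM
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
        window_days: 730
  - name: elevated_hba1c_pair
    criteria:
      - data_type: LAB
        code_set: hba1c
        min_count: 2
        distinct_days: true
        predicate: {op: ">=", threshold: 6.5, unit: "%"}
  - name: diagnosis_plus_medication
    criteria:
      - data_type: DX
        code_set: t2d_dx
        min_count: 1
      - data_type: RX
        code_set: t2d_rx
        min_count: 1
  - name: diagnosis_plus_lab
    criteria:
      - data_type: DX
        code_set: t2d_dx
        min_count: 1
      - data_type: LAB
        code_set: hba1c
        min_count: 1
        predicate: {op: ">=", threshold: 6.5, unit: "%"}
  - name: medication_plus_lab
    criteria:
      - data_type: RX
        code_set: t2d_rx
        min_count: 1
      - data_type: LAB
        code_set: hba1c
        min_count: 1
        predicate: {op: ">=", threshold: 6.5, unit: "%"}
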