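# eMERGE style definition: diagnosis must be corroborated by medication or
# laboratory evidence, or repeated elevated HbA1c alone; no diagnosis-only,
# medication-only or medication+laboratory-only pathway.
name: EMERGE
pathways:
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
  - name: elevated_hba1c_pair
    criteria:
      - data_type: LAB
        code_set: hba1c
        min_count: 2
        distinct_days: true
        predicate: {op: ">=", threshold: 6.5, unit: "%"}
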