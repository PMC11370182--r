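# Durham Diabetes Coalition style definition: each data type can qualify
# on its own, with a two-diagnosis requirement on the diagnosis route.
name: DDC
pathways:
  - name: repeated_diagnoses
    criteria:
      - data_type: DX
        code_set: t2d_dx
        min_count: 2
        distinct_days: true
  - name: any_medication
    criteria:
      - data_type: RX
        code_set: t2d_rx
        min_count: 1
  - name: elevated_hba1c
    criteria:
      - data_type: LAB
        code_set: hba1c
        min_count: 1
        predicate: {op: ">=", threshold: 6.5, unit: "%"}
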