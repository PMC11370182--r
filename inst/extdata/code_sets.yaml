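# Default code sets for the shipped type-2-diabetes definitions.
# ICD-10 sets match by dot-stripped prefix (family codes cover child codes);
# RxNorm codes are ingredient-level CUIs; LOINC codes match exactly.
t2d_dx:
  code_system: ICD10
  match_mode: prefix
  codes: [E11]
t2d_dx_adjacent:
  # Diabetes-adjacent families used as inaccuracy replacement pools, never
  # as qualifying evidence: secondary, drug-induced, other-specified and
  # gestational diabetes.
  code_system: ICD10
  match_mode: prefix
  codes: [E08, E09, E13, O24]
t2d_rx:
  code_system: RXNORM
  match_mode: exact
  codes:
    - "6809"     # metformin
    - "4821"     # glipizide
    - "4815"     # glyburide
    - "25789"    # glimepiride
    - "33738"    # pioglitazone
    - "593411"   # sitagliptin
    - "857974"   # saxagliptin
    - "1373458"  # canagliflozin
    - "1488564"  # dapagliflozin
    - "1545653"  # empagliflozin
    - "475968"   # liraglutide
    - "60548"    # exenatide
    - "274783"   # insulin glargine
    - "86009"    # insulin lispro
    - "51428"    # insulin aspart
hba1c:
  code_system: LOINC
  match_mode: exact
  codes: ["55454-3", "4548-4"]
glucose_random:
  code_system: LOINC
  match_mode: exact
  codes: ["2345-7"]
glucose_fasting:
  code_system: LOINC
  match_mode: exact
  codes: ["1558-6"]
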