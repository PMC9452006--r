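# Desk-scale experiment cell: ICD-9 input, validity check on,
# knowledge constraint off.
coding: icd9
validity_check: true
knowledge_constraint: false
split_seed: 1
n_records: 2000
n_folds: 5
model:
  architecture: lstm
  attention: general
  train_steps: 2000
beam:
  k: 5
  max_length: 18
paths:
  output_dir: mortseq_output
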