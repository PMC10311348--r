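# Example sigpept run configuration. Every key is optional; omitted keys
# keep package defaults. Quote "N" or leave it bare (both are accepted).
model:
  d: 64
  dS: 16
  H: 4
  L_enc: 2
  L_dec: 2
  ed: 256
  N: 70
  dropout: 0.1
  dropout_enc: 0.0
train:
  lr_encoder: 4.0e-4   # from-scratch compact preset; pretrained encoders use 1.0e-5
  lr_decoder: 4.0e-4
  epochs: 22
  batch_size: 4
  seed: 1
  adam_beta2: 0.98
  swa_enabled: true
grammar:
  seq_len_range: [40, 70]
  n_region: [2, 10]
  h_region: [7, 15]
  c_region: [3, 7]
  br_region: [2, 8]
  axa: true
codes:
  Sec/SPaseI: S
  Sec/SPaseII: L
  Sec/SPaseIV: P
  TAT/SPaseI: T
  TAT/SPaseII: W
  intracellular: I
  transmembrane: M
  extracellular: O
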