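# example run configuration: a C.C mismatch at domain position 7
system:
  toehold_length: 4
  domain_length: 20
  mismatch_position: 7
  mismatch_type: CC
  target: ACTCCATGATCTCTGAGTGTGTCA
  temperature: 25
rates:
  positions: [2, 3, 4, 5, 7, 15, 17]
global:
  seed: 1
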