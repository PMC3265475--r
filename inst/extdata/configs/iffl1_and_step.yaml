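name: iffl1_and_step
description: 'IFFL-1 AND gate, sustained step: single expression pulse'
signal:
  type: step
  on_time: 1.0
  off_time: 6.0
motif:
  topology: ffl
  ffl_type: 5.0
  gate: AND
  stages:
    'Y':
      synth_off: 0.0
      synth_on: 1.5
      degradation: 1.0
    Z:
      synth_off: 0.0
      synth_on: 1.5
      degradation: 1.0
  thresholds:
    k_xy: 0.5
    k_xz: 0.5
    k_yz: 0.75
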