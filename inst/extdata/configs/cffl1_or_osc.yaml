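name: cffl1_or_osc
description: CFFL-1 with OR gate under the symmetric oscillation
signal:
  type: periodic
  profile: symmetric
  period: 1.0
experiment:
  periods:
  - 0.1
  - 0.177828
  - 0.316228
  - 0.562341
  - 1.0
  - 1.77828
  - 3.16228
  - 5.62341
  - 10.0
  - 17.7828
  - 31.6228
  - 56.2341
  - 100.0
motif:
  topology: ffl
  ffl_type: 1.0
  gate: OR
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
    k_xy: 0.1
    k_xz: 0.75
    k_yz: 1.3
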