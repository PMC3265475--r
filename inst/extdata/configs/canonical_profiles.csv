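profile,time,value
left_skewed,0,0
left_skewed,0.05,0.1
left_skewed,0.1,0.75
left_skewed,0.1333,1
left_skewed,0.35,0.75
left_skewed,0.8,0.1
left_skewed,1,0
symmetric,0,0
symmetric,0.125,0.1
symmetric,0.375,0.75
symmetric,0.5,1
symmetric,0.625,0.75
symmetric,0.875,0.1
symmetric,1,0
right_skewed,0,0
right_skewed,0.2,0.1
right_skewed,0.65,0.75
right_skewed,0.8667,1
right_skewed,0.9,0.75
right_skewed,0.95,0.1
right_skewed,1,0
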