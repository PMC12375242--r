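# Cholesterol-conjugated construct chemistry (illustrative default
# positions): the second-generation pattern plus a 3' cholesterol conjugate
# on the sensor via a triethylene-glycol spacer for carrier-free uptake.
name: cholConj
description: secondG pattern plus sensor 3' cholesterol-TEG conjugate
rules:
  - strand: sensor
    chemistry: sugar
    value: LNA
    region: toehold
    sub: [-3, -2, -1]
  - strand: sensor
    chemistry: sugar
    value: LNA
    region: middle_toehold
  - strand: sensor
    chemistry: backbone
    value: PS
    positions: [1, 2]
  - strand: sensor
    chemistry: backbone
    value: PS
    region: all
    sub: [-3, -2, -1]
  - strand: guide
    chemistry: backbone
    value: PS
    positions: [23, 24]
  - strand: guide
    chemistry: sugar
    value: 2OMe
    region: pair_region
  - strand: sensor
    chemistry: conjugate
    value: cholesterol-TEG
    terminal: three_prime
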