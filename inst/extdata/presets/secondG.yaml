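# Second-generation construct chemistry (illustrative default positions):
# the first-generation pattern plus 2'-O-methyl across the guide pairing
# region for nuclease resistance and reduced off-target loading.
name: secondG
description: firstG pattern plus 2'-O-methyl guide pairing region
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
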