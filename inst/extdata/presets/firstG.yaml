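# First-generation construct chemistry (illustrative default positions).
# Qualitative pattern: LNA substitutions for binding affinity, sparse
# ("reduced") terminal phosphorothioates on the sensor, and an LNA at the
# middle toehold. Edit positions before ordering a synthesis.
name: firstG
description: LNA-stabilized sensor toehold and middle toehold; sparse terminal PS
rules:
  - strand: sensor
    chemistry: sugar
    value: LNA
    region: toehold
    sub: [-3, -2, -1]       # last three toehold residues
  - strand: sensor
    chemistry: sugar
    value: LNA
    region: middle_toehold
  - strand: sensor
    chemistry: backbone
    value: PS
    positions: [1, 2]       # two 5'-terminal linkages
  - strand: sensor
    chemistry: backbone
    value: PS
    region: all
    sub: [-3, -2, -1]       # last three residues -> the two 3'-terminal linkages
  - strand: guide
    chemistry: backbone
    value: PS
    positions: [23, 24]     # protect the 3' overhang linkages
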