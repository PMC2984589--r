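# atom-name aliases: ALIAS CANONICAL [RESIDUE]
# digit-first hydrogen names (1HB -> HB1) are rewritten in code
HN H
HT1 H1
HT2 H2
HT3 H3
OT1 O
OT2 OXT
OCT1 O
OCT2 OXT
HN1 H1
HN2 H2
HN3 H3
OW O HOH
HW1 H1 HOH
HW2 H2 HOH
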