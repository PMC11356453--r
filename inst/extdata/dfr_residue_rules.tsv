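ref_position	allowed	role
# NADPH-binding region positions are placeholders pending curation of a
# full residue set; the functional screen for DFR rests on the presence of
# the 26-residue substrate-binding region (anchor-2 .. anchor+23), which is
# checked structurally by type_sequences(), not through this table.
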