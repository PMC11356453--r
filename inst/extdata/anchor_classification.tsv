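family	residue	type_label	substrates	confidence	note
DFR	N	DFR_N	DHK,DHQ,DHM	reported	accepts all three dihydroflavonols
DFR	D	DFR_D	DHQ,DHM	reported	prefers DHQ and DHM
DFR	A	DFR_A	DHK	reported	high DHK affinity
DFR	L	DFR_other	DHK	reported	leucine restricts the substrate to DHK
FLS	H	FLS_H	DHK,DHQ	hypothesized	accepts DHK and DHQ
FLS	F	FLS_F	DHK	hypothesized	prefers DHK
FLS	Y	FLS_Y	DHQ	hypothesized	prefers DHQ
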