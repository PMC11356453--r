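ref_position	allowed	role
68	G	2-ODD fold
75	H	2-ODD fold
207	P	2-ODD fold
261	G	2-ODD fold
132	HFY	substrate preference / DHQ binding
134	F	DHQ binding
202	K	DHQ binding
293	F	DHQ binding
295	E	DHQ binding
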