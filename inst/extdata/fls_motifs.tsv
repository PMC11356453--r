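name	pattern	scope
fls_unique_1	PxxxIRxxxEQP	any
fls_unique_2	SxxTxLVP	any
fe_binding	Hx[DE]x{40,150}H	any
og_binding	RxS	cterm
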