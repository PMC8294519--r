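# protein	tat	score	cleavage
p1	YES	0.84	29
p2	NO	0.05	-
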