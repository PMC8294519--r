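# protein	signal	score	cleavage
p1	YES	0.91	23
p2	NO	0.12	-
p3	YES	0.77	31
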