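# protein	tm	sp	prediction
p1	0	Y	c24/25
p2	2	0	35-57,70-92
p3	1	Y	c22/23;88-110
p4	0	0	-
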