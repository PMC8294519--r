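# protein	class	score	cleavage
p1	SpII	14.2	18
p2	CYT	1.1	-
p3	SpI	9.8	27
p4	TMH	6.3	-
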