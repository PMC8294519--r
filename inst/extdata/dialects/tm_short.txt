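# protein	helices	topology
p1	2	12-34,56-78
p2	0	-
p3	1	101-123
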