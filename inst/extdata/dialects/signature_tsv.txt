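# protein	accession	start	end	score	go
p1	IPR019931	180	215	52.1	GO:0005618
p2	PS51257	1	20	18.5	-
p3	IPR010310	5	95	33.0	GO:0005576|GO:0005618
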