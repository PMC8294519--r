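go_id	tag
GO:0005576	EXTRA
GO:0005618	CW
GO:0009986	CW
GO:0005886	TM
GO:0016020	TM
GO:0005737	CYTO
GO:0005829	CYTO
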