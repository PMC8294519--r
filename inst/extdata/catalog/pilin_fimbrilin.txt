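# Starter list: pseudo-pilin and fimbrilin signatures (hint-level).
IPR012902  # prokaryotic N-terminal methylation site (type IV pilin-like)
IPR016940  # fimbrial isopeptide-forming adhesin (starter)
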