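accession	pathway
IPR010310	Wss/T7SSb-like
IPR023840	Wss/T7SSb-like
IPR001492	FEA-like
IPR025644	SecA2-like
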