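# Starter list: covalent (sortase-mediated) cell-wall anchoring.
IPR019931  # LPXTG cell-wall anchor domain
TIGR01167  # LPXTG cell-wall anchor motif
CW_COVALENT_MOTIF  # label emitted by the built-in LPXTG scan
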