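# Starter list: lipoprotein attachment signatures.
PS51257    # prokaryotic membrane lipoprotein lipid attachment site
IPR016367  # substrate-binding lipoprotein family (starter)
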