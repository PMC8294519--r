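# Starter list: signatures of non-classical secretion substrates.
# One accession per line; '#' starts a comment.
IPR010310  # WXG100 / ESAT-6-like protein family (T7SSb substrates)
IPR001492  # bacterial flagellin (flagellar export apparatus substrate)
IPR023840  # EsxB-like T7SSb substrate
IPR025644  # SecA2-dependent substrate family (starter placeholder)
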