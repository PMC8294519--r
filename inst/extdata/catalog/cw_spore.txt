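# Starter list: spore coat / cortex associated signatures.
IPR014867  # spore coat assembly protein family
IPR007247  # spore coat protein CotJB-like (starter)
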