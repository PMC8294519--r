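# Starter list: twin-arginine translocation associated signatures.
IPR006311  # Tat (twin-arginine) signal sequence
IPR019546  # Tat signal, conserved site
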