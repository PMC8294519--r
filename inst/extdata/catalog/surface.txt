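# Starter list: surface-associated adhesion signatures (hint-level).
IPR008966  # adhesion domain superfamily
IPR011252  # fibrinogen-binding surface adhesin (starter)
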