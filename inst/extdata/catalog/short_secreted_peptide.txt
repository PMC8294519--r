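# Starter list: short secreted peptides (lantibiotics, bacteriocins).
IPR006079  # class II bacteriocin
IPR007682  # lantibiotic, gallidermin/epidermin family
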