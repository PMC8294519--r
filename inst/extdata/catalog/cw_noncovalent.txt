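# Starter list: non-covalent cell-wall binding domains and repeats.
IPR018392  # LysM peptidoglycan-binding domain
IPR003646  # SH3b bacterial cell-wall binding domain
IPR018337  # choline-binding repeat
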