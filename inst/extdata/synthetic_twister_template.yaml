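name: twister-like-synthetic
cleavage_site: 5
linker: GAGCGGCCAACAAACGTATTAATA
coordinates: 0-based
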