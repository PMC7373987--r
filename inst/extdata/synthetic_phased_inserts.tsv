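# anchor: GGG
insert_id	sequence	proportion
ins9	GTTCCTATT	0.25
ins12	AACTAAGCGAAT	0.25
ins15	TGAAGGTACTTACAA	0.25
ins18	CCGGTCCGACCGTTCCTA	0.25
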