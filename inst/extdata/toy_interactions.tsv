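protein_a	protein_b	score
GATA4	TBX5	0.9
NANOG	POU5F1	0.95
GATA4	NANOG	0.15
EZH2	SUZ12	0.99
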