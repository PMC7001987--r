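format-version: 1.2
ontology: toy-anatomy

[Term]
id: TA:0000001
name: tissues and cell types

[Term]
id: TA:0000002
name: cardiovascular system
is_a: TA:0000001 ! tissues and cell types

[Term]
id: TA:0000003
name: neurological system
is_a: TA:0000001 ! tissues and cell types

[Term]
id: TA:0000004
name: embryonic structure
is_a: TA:0000001 ! tissues and cell types

[Term]
id: TA:0000005
name: heart
synonym: "cardiac muscle tissue" EXACT []
is_a: TA:0000002 ! cardiovascular system

[Term]
id: TA:0000006
name: cardiomyocyte
is_a: TA:0000005 ! heart

[Term]
id: TA:0000007
name: aorta
is_a: TA:0000002 ! cardiovascular system

[Term]
id: TA:0000008
name: brain
is_a: TA:0000003 ! neurological system

[Term]
id: TA:0000009
name: neuron
is_a: TA:0000003 ! neurological system

[Term]
id: TA:0000010
name: embryonic stem cell
synonym: "hESC" EXACT []
is_a: TA:0000004 ! embryonic structure

[Term]
id: TA:0000011
name: H1 cell line
is_a: TA:0000010 ! embryonic stem cell

[Term]
id: TA:0000012
name: kidney
is_a: TA:0000001 ! tissues and cell types
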