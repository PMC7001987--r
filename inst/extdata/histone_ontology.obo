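format-version: 1.2
ontology: histone-modifications

[Term]
id: HM:0000001
name: histone modification

[Term]
id: HM:0000002
name: At active promoters
is_a: HM:0000001 ! histone modification

[Term]
id: HM:0000003
name: At poised promoters
is_a: HM:0000001 ! histone modification

[Term]
id: HM:0000004
name: At active enhancers
is_a: HM:0000001 ! histone modification

[Term]
id: HM:0000005
name: At repressed regions
is_a: HM:0000001 ! histone modification

[Term]
id: HM:0000006
name: H3K4me3
is_a: HM:0000002 ! At active promoters
is_a: HM:0000003 ! At poised promoters

[Term]
id: HM:0000007
name: H3K27ac
is_a: HM:0000002 ! At active promoters
is_a: HM:0000004 ! At active enhancers

[Term]
id: HM:0000008
name: H3K4me1
is_a: HM:0000003 ! At poised promoters
is_a: HM:0000004 ! At active enhancers

[Term]
id: HM:0000009
name: H3K27me3
is_a: HM:0000005 ! At repressed regions

[Term]
id: HM:0000010
name: H3K9me3
is_a: HM:0000005 ! At repressed regions
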