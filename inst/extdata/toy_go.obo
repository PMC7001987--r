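format-version: 1.2
ontology: toy-go

[Term]
id: TG:0000001
name: molecular function

[Term]
id: TG:0000002
name: DNA-binding transcription factor activity
is_a: TG:0000001 ! molecular function

[Term]
id: TG:0000008
name: catalytic activity
is_a: TG:0000001 ! molecular function

[Term]
id: TG:0000003
name: GATA4
is_a: TG:0000002 ! DNA-binding transcription factor activity

[Term]
id: TG:0000004
name: TBX5
is_a: TG:0000002 ! DNA-binding transcription factor activity

[Term]
id: TG:0000005
name: NANOG
is_a: TG:0000002 ! DNA-binding transcription factor activity

[Term]
id: TG:0000006
name: POU5F1
synonym: "OCT4" EXACT []
is_a: TG:0000002 ! DNA-binding transcription factor activity

[Term]
id: TG:0000007
name: EZH2
is_a: TG:0000008 ! catalytic activity
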