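ontology	class_id
cell_type	TA:0000002
cell_type	TA:0000003
cell_type	TA:0000004
target_go	TG:0000002
target_go	TG:0000008
target_histone	HM:0000002
target_histone	HM:0000003
target_histone	HM:0000004
target_histone	HM:0000005
transcription_factor	TG:0000002
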