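g1	TA:0000004
g2	TA:0000004
g3	TA:0000003
g4	TA:0000003
g1	TB:0000002
g2	TB:0000002
g5	TB:0000003
g6	TB:0000003
g9	TA:0000005
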