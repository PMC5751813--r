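# gene_a	gene_b	weight
g1	g2	1
g2	g3	0.2
g3	g4	0.6
g3	g5	0.8
g4	g6	0.8
g5	g6	1
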