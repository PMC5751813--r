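# term1	term2	label
TA:0000003	TB:0000003	positive
TA:0000002	TB:0000003	random
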