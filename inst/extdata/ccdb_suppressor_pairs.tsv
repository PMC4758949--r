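pos_x	pos_y
5	36
5	81
18	63
18	90
36	63
83	54
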