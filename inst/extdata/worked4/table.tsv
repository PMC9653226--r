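cell	target_1	target_2	target_3	target_4	target_5
cell_1	3	3	2	2	2
cell_2	3	3	2	2	2
cell_3	3	3	0	2	2
cell_4	3	3	0	2	2
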