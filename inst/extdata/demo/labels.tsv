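protein_id	label
pos_1	1
pos_2	1
pos_3	1
neg_1	0
neg_2	0
neg_3	0
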