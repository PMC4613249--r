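protein_id	interpro_id
pos_1	IPR000436
pos_1	IPR000538
pos_1	IPR003599
pos_1	IPR007110
pos_1	IPR013106
pos_1	IPR018097
pos_1	IPR018378
pos_2	IPR000152
pos_2	IPR001881
pos_2	IPR007110
pos_2	IPR013106
pos_2	IPR013783
pos_2	IPR018097
pos_2	IPR018378
pos_3	IPR000152
pos_3	IPR001304
pos_3	IPR003599
pos_3	IPR007110
pos_3	IPR013032
pos_3	IPR016186
pos_3	IPR018097
pos_3	IPR018378
neg_2	IPR013032
neg_2	IPR016187
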