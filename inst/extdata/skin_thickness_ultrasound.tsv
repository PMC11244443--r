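subject	skin_fat_thickness_cm	skin_thickness_cm
S1	1.217	0.2
S2	1.633	0.27
S3	0.983	0.163
S4	0.897	0.15
S5	0.82	0.136
S6	0.413	0.07
S7	0.587	0.097
S8	0.56	0.09
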