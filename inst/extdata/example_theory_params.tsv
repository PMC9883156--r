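trait	r	h_eq2	h_snp2	M	n
height	0.25	0.85	0.45	20000	140000
bmi	0.2	0.6	0.25	20000	140000
t2d	0.1	0.4	0.2	20000	140000
dummy	0	0.5	0.5	10000	140000
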