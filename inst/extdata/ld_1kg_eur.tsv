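SNP_A	SNP_B	R2	DP	POP
rs7903146	rs7074440	0.91	0.95	EUR
rs7903146	rs34872471	0.99	1.00	EUR
rs7903146	rs11196205	0.45	0.92	EUR
rs4462262	rs4579060	0.85	0.90	EUR
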