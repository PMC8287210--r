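r	m	count
0.30	0.12	220
0.45	0.16	410
0.60	0.21	520
0.80	0.26	480
1.00	0.30	340
1.25	0.34	230
1.55	0.38	120
1.90	0.42	60
2.40	0.46	20
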