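comparison	metric	test	roi_set	bias	error	rel_bias_pct	rel_error_pct
retest	g	session2	high_snr	0.0021	0.0102	4.57	22.17
retest	avf	session2	high_snr	0.0006	0.0156	0.79	20.53
retest	mvf	session2	high_snr	-0.0031	0.0076	-8.38	20.54
method	g	NONE	high_snr	-0.041	0.017	-89.13	36.96
method	g	DATA_DRIVEN	high_snr	0.014	0.005	30.44	10.87
method	avf	NONE	high_snr	-0.031	0.012	-40.79	15.79
method	avf	DATA_DRIVEN	high_snr	0.011	0.004	14.47	5.26
method	mvf	NONE	high_snr	0.053	0.022	143.24	59.46
method	mvf	DATA_DRIVEN	high_snr	-0.018	0.006	-48.65	16.22
method	mvf	NONE	whole_wm	0.033	0.048	36.48	52.75
method	mvf	DATA_DRIVEN	whole_wm	-0.012	0.022	-13.08	23.96
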