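i_a0	i_a_inf	g_a0	g_b0	g_a_inf	g_b_inf
uA_per_cm2	uA_per_cm2	uS	uS	uS	uS
0.08	6.40	12.87	360.00	689.04	480.47
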