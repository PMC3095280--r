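node	k2p	s_dif	ks	ns_dif	ka	ka_ks
1A	0.291	46.5	1.82	27.4	0.123	0.068
1B	0.296	36.5	1.00	17.5	0.086	0.090
1C	0.274	41.0	1.55	30.3	0.147	0.095
1E	0.326	49.0	>2.0	23.0	0.122	<0.061
3	0.094	17.0	0.309	11.8	0.050	0.163
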