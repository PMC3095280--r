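region	category	s_dif	s_pos	ks	ns_dif	ns_pos	ka	ka_ks	p
PHYA1_hinge	D-D	2.0	67.33	0.303	0.0	241.67	0.000	0.000	0.049
PHYA1_hinge	D-T	2.25	67.17	0.102	0.0	241.84	0.000	0.000	0.039
PHYA1_hinge	T-T	2.5	67	0.038	0.0	242.00	0.000	0.000	0.030
PHYA2_hinge	D-D	1.0	66.42	0.015	3.0	242.58	0.125	8.224	0.622
PHYA2_hinge	D-T	1.0	66.38	0.015	2.0	242.63	0.065	4.247	0.504
PHYA2_hinge	T-T	1.0	66.33	0.015	1.0	242.67	0.004	0.270	0.386
PHYB_2.1kb	D-D	8.0	377.33	0.022	7.0	1293.67	0.005	0.251	0.010
PHYB_2.1kb	D-T	9.0	377.34	0.024	8.0	1293.63	0.006	0.256	0.006
PHYB_2.1kb	T-T	10	377.42	0.027	9.0	1293.58	0.007	0.300	0.004
PHYC_hinge	D-D	3.0	60.83	0.051	1.0	230.17	0.004	0.086	0.032
PHYC_hinge	D-T	3.25	60.67	0.055	1.25	230.09	0.005	0.103	0.035
PHYC_hinge	T-T	3.5	60.5	0.06	1.5	230.00	0.007	0.119	0.038
PHYC_1.0kb	D-D	7.0	224.67	0.032	3.0	795.33	0.004	0.120	0.002
PHYC_1.0kb	D-T	8.0	224.84	0.037	4.5	795.17	0.006	0.156	0.003
PHYC_1.0kb	T-T	9.0	225	0.041	6.0	795.00	0.008	0.184	0.002
PHYE_hinge	D-D	4.0	60.42	0.069	1.0	206.58	0.005	0.071	0.012
PHYE_hinge	D-T	3.75	60.46	0.065	0.5	206.54	0.003	0.042	0.015
PHYE_hinge	T-T	3.5	60.5	0.06	0.0	206.50	0.000	0.000	0.008
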