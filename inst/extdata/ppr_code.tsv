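aa6	aa1p	pA	pC	pG	pU
T	N	0.70	0.08	0.16	0.06
T	D	0.10	0.03	0.83	0.04
S	N	0.76	0.10	0.06	0.08
S	D	0.10	0.06	0.78	0.06
N	D	0.05	0.15	0.04	0.76
N	S	0.09	0.66	0.06	0.19
N	N	0.06	0.43	0.05	0.46
N	T	0.07	0.39	0.08	0.46
G	N	0.30	0.18	0.22	0.30
A	D	0.16	0.25	0.09	0.50
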