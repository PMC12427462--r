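pair	diet_a	diet_b	total_g_a	total_g_b
CDxT150	CD	T150	988	1699
CDxT300	CD	T300	759	1783
T150xT300	T150	T300	1484	1047
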