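domain	CT_observed	CT_expected	CD_observed	CD_expected	UC_observed	UC_expected	description
PF00036	35	110	16	100	17	97	Helix-loop-helix motif of a large family of calcium-binding proteins (EF-hand_1)
PF00069	35255	33790	16544	30657	13444	29731	Protein kinase domain (Pkinase)
PF13895	149	76	12	69	10	67	Immunoglobulin domain (Ig_2)
PF00612	8	20	9	18	9	17	IQ calmodulin-binding motif (IQ)
PF00149	44022	43137	41838	39136	41095	37955	Calcineurin-like phosphoesterase (Metallophos)
PF13202	1962	3421	2420	3104	2524	3010	EF hand (EF-hand_5)
PF13499	2192	1226	696	1113	724	1079	EF-hand domain pair (EF-hand_7)
PF13405	60	55	56	50	58	49	EF-hand domain (EF-hand_6)
PF00063	2	3	2	3	2	3	Myosin head motor domain (Myosin_head)
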