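gene	Egg	7 hpf	16 hpf	29 hpf
GAPDH	1118.136	5422.3220000000001	2886.056	4009.1260000000002
ODC	559.06799999999998	2711.1610000000001	1443.028	2004.5630000000001
HPRT	279.53399999999999	1355.5805	721.51400000000001	1002.2815000000001
MAOA	698.83500000000004	2982.2771000000002	1875.9364	2405.4756000000002
HTR6	670.88159999999993	1409.8037200000001	259.74504000000002	801.82520000000011
HTR1A	173.31108	677.79025000000001	173.16335999999998	400.91260000000005
SERT	0.55906800000000001	3.2533931999999997	1.2987252	2.0045630000000001
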