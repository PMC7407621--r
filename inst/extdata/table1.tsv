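# Random-library secondary screening: catalytic efficiency (1/M/s) and TM (C).
clone	kcat_km	tm
GNCA4-WT	3047 ± 282	80
3C11	608 ± 68	77
4B4	1770 ± 126	81
8F11	5980 ± 117	80
6D5	2476 ± 420	81
7C1	600 ± 56	72
8E12	2222 ± 167	70
6A12	1036 ± 159	79
7D1	1880 ± 155	67
2H4	2280 ± 146	ND
5H8	2066 ± 67	64
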