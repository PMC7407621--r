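# Background and the 20 stability-designed variants at pH 7, 5% acetonitrile:
# kcat (1/s), KM (mM), kcat/KM (1/M/s), TM (C).
variant	kcat	km	kcat_km	tm
GNCA4-WT	5.1 ± 0.8	3.7 ± 0.8	1360 ± 101	78.0
GNCA4-1	0.22 ± 0.03	2.2 ± 0.6	102 ± 12	79.1
GNCA4-2	28.9 ± 15	8.12 ± 5	3519 ± 401	78.4
GNCA4-3	4.5 ± 1.6	3.3 ± 1.7	1348 ± 238	79.1
GNCA4-4	0.12 ± 0.14	14 ± 18	8.7 ± 1.2	78.0
GNCA4-5	2.8 ± 0.2	2.3 ± 0.3	1214 ± 11	77.5
GNCA4-6	23 ± 18	24 ± 20	944 ± 54	78.8
GNCA4-7	0.54 ± 0.06	2.8 ± 0.5	190 ± 12	77.7
GNCA4-8	8.2 ± 1.2	2.8 ± 0.7	2856 ± 247	77.6
GNCA4-9	0.17 ± 0.12	5.3 ± 5	31.7 ± 7.3	76.8
GNCA4-10	0.7 ± 0.23	4.8 ± 2	190 ± 22	79.6
GNCA4-11	2.7 ± 0.35	1.8 ± 0.4	1403 ± 153	76.4
GNCA4-12	28 ± 12	6.8 ± 3.7	4127 ± 460	76.0
GNCA4-13	0.4 ± 0.07	2.9 ± 0.7	132 ± 12	75.1
GNCA4-14	1.06 ± 0.07	1.9 ± 0.2	560 ± 32.5	79.6
GNCA4-15	3.1 ± 1.8	9.1 ± 6.3	339 ± 38	77.1
GNCA4-16	1.8 ± 0.07	3.4 ± 1.9	532 ± 96	81.2
GNCA4-17	0.06 ± 0.01	4.4 ± 1.5	15 ± 1.4	77.1
GNCA4-18	4.3 ± 0.4	8.2 ± 0.8	524 ± 9.3	80.9
GNCA4-19	7.1 ± 1.5	2.9 ± 0.9	2366 ± 271	77.9
GNCA4-20	0.3 ± 0.02	1.2 ± 0.1	232 ± 16	83.9
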