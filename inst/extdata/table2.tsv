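# Calibration single mutants: kcat (1/s), KM (mM), kcat/KM (1/M/s),
# experimental and calculated activation free energies (kcal/mol).
variant	kcat	km	kcat_km	dg_exp	dg_calc
GNCA4-WT	2.6 ± 0.44	1.5 ± 0.4	1705 ± 139	16.7	16.2 ± 0.1
G62S	3.64 ± 0.83	1.25 ± 0.45	2911 ± 401	16.7	16.3 ± 0.2
A146G	5.44 ± 0.77	2.34 ± 0.44	2328 ± 112	16.5	16.5 ± 0.2
A173V	3.78 ± 0.19	1.53 ± 0.12	2464 ± 62	16.7	16.9 ± 0.3
L265Q	4.4 ± 1.01	1.8 ± 0.58	2447 ± 242	16.6	16.7 ± 0.2
R256K	6.13 ± 1.76	3.2 ± 1.1	1542 ± 369	16.4	16.9 ± 0.2
R256A	4.80 ± 1.40	4.7 ± 1.6	875 ± 15	16.5	16.6 ± 0.3
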