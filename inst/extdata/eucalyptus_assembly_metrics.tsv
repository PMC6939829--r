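assembly	length	contig_count	n50	busco_complete	busco_complete_pct	busco_duplicated	busco_duplicated_pct	busco_fragmented	busco_fragmented_pct	lai	ploidy	short_mapping_rate	short_error_rate	long_mapping_rate	long_error_rate	cgal	sv_total
Canu_1kb	622218742	895	1502325	1346	93.47	183	12.71	23	1.60	7.04	1.24	96.02	0.0061	91.73	0.1661	-1959000	4243
Canu_35kb	585785283	655	2258674	1345	93.40	138	9.58	29	2.01	5.34	1.17	95.52	0.0066	92.64	0.1677	-2226000	5043
SMARTdenovo_1kb	514714831	364	2092790	1342	93.19	100	6.94	27	1.88	7.02	1.03	98.42	0.0080	92.38	0.1678	-4275000	5940
SMARTdenovo_35kb	504515539	370	2178079	1341	93.13	100	6.94	30	2.08	6.73	1.01	98.35	0.0082	92.20	0.1679	-5869476	6024
Flye_1kb	528563896	2947	295613	1344	93.33	100	6.94	31	2.15	5.70	1.06	94.86	0.0077	93.04	0.1694	-2536000	7137
Flye_35kb	516992152	2548	385290	1336	92.78	90	6.25	31	2.15	6.50	1.03	94.24	0.0080	92.34	0.1699	-2726000	7458
Marvel_35kb	537615613	730	1202845	1180	81.94	153	10.63	32	2.22	3.77	1.08	87.37	0.0075	85.18	0.1689	-4451000	5162
MaSuRCA_1kb	594528099	415	3234447	1362	94.58	201	13.96	21	1.46	9.27	1.19	94.91	0.0060	91.57	0.1656	-1774303	4020
MaSuRCA_35kb	594871467	416	3234549	1362	94.58	200	13.89	21	1.46	9.31	1.19	94.92	0.0060	91.49	0.1655	-1790386	4017
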