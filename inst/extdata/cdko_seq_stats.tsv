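Sample	Reads	Mapped	Mapped_pct	Zero_Counts	Zero_Counts_pct	Gini_Index	Above_Threshold	Above_Threshold_pct
Library/Plasmid	9272549	8159448	88.00	141	0.27	0.05	48921	92.48
T0_1	12431419	11383720	91.57	892	1.69	0.06	47101	89.04
T0_2	15647051	14281485	91.27	722	1.36	0.06	47669	90.11
T0_3	15104601	13610181	90.11	1371	2.59	0.05	47547	89.88
Tend_1	10004498	9114027	91.10	109	0.21	0.05	50658	95.76
Tend_2	15386447	13994094	90.95	48	0.09	0.05	51875	98.06
Tend_3	15837762	14264603	90.07	39	0.07	0.05	51866	98.05
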