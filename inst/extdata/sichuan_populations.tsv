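pop_no	population	longitude	latitude	FN	FT	MN	MT	fst	fis_f	fis_m	theta_s	group
1	PZLMS	103.8073	31.2438	2	14	7	1	0.24	-0.64	-0.64	4.41	WEST
2	PZCF	103.8001	31.1056	6	5	20	4	0.24	-0.19	-0.58	7.30	WEST
3	QCS	103.3929	30.9260	2	12	1	4	0.16	-0.45	-0.42	5.11	WEST
4	DYYEC	103.4399	30.7081	36	32	30	10	0.23	-0.21	-0.53	5.52	WEST
5	DYGTS	103.4658	30.5847	0	26	1	10	0.23	-0.79	-0.59	3.44	WEST
6	QLDZ	103.2558	30.3167	41	0	9	0	0.18	-0.40	-0.51	4.15	WEST
7	QLTTS	103.1128	30.2775	21	12	18	3	0.17	-0.24	-0.44	5.77	WEST
8	EMPX	103.4675	29.6888	25	2	12	0	0.17	-0.12	-0.37	4.65	WEST
9	DGTX	104.0202	27.8064	28	0	21	0	0.05	0.13	-0.04	16.68	EAST
10	SYKKS	107.1643	28.2331	11	0	20	0	0.05	-0.14	-0.03	7.47	EAST
11	ZYST	106.1491	25.7158	10	0	4	0	-0.01	0.39	-0.09	5.09	EAST
12	GDYX	107.3123	26.3676	18	0	28	0	0.02	0.26	0.45	15.97	EAST
13	HJSP	110.1707	27.1766	31	0	26	0	0.08	0.30	0.15	15.35	EAST
14	BJHL	109.7746	28.4888	15	0	15	0	0.02	0.32	0.15	8.25	EAST
15	TSCW	114.6774	29.4369	26	0	31	0	0.08	0.10	0.43	12.89	EAST
16	XSGQ	110.6109	31.2419	31	0	6	0	0.37	0.17	-0.27	6.39	EAST
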