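population	theta_Y	theta_X	theta_A	e_theta_Y	e_theta_X	e_theta_A	theta_XT	theta_XN
PZLMS	0.21	1.96	4.38	0.54	1.63	2.17	0.00	0.41
PZCF	0.35	2.74	18.87	0.77	2.31	3.08	0.00	1.53
QCS	0.19	2.35	37.51	0.64	1.91	2.54	0.13	2.18
DYYEC	0.00	1.48	17.13	0.37	1.11	1.48	0.25	0.31
DYGTS	0.05	1.66	3.64	0.43	1.28	1.71	0.02	0.90
QLDZ	0.06	2.11	6.22	0.54	1.63	2.17	NA	NA
QLTTS	0.13	2.79	21.27	0.73	2.19	2.92	NA	NA
EMPX	0.00	1.94	22.52	0.49	1.46	1.94	NA	NA
Average	0.12	2.13	16.44	0.56	1.69	2.25	0.08	1.07
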