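system	MP2	M06-2X	cycle1	cycle2	cycle3	cycle4	reference
1	6.50	7.39	11.07	2.61	6.72	6.72
2	6.93	7.72	10.78	3.34	7.12	7.12
3	6.35	7.13	11.14	1.96	6.70	6.70
4	6.05	7.30	6.63	0.01	3.52	6.63
5	6.45	7.28	10.11	2.01	6.31	6.31
6	6.53	7.38	10.56	2.44	6.55	6.55
7	6.76	7.58	10.36	2.77	6.76	6.76	5.74
8	6.77	7.54	10.06	3.18	7.06	7.06
9	6.86	7.62	12.78	5.56	9.57	7.00	8.52
10	6.89	9.74	12.40	5.54	9.06	6.77
11	6.79	7.54	12.32	4.33	8.22	7.10	8.05
12	8.02	8.90	15.12	6.34	11.08	7.93
13	8.26	8.99	13.78	4.05	8.94	8.94	4.40
14	7.12	8.08	14.38	2.44	7.70	7.70
15	7.44	8.37	12.76	1.80	7.58	7.58
16	7.53	8.42	12.88	2.69	7.86	7.86
17	5.07	5.54	6.70	-6.75	0.47	4.96
18	4.80	5.34	4.45	-7.52	-1.53	4.45
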