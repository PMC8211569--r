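gene	BLCA	BRCA	COAD	ESCA	HNSC	KIRC	LIHC	LUAD	PRAD	STAD	THCA	UCEC
ADH1B	-4.40	-4.86	-4.06	-2.15	-3.41	-2.67	-1.16	-3.19	-1.66	-1.83	-3.44	-7.03
ALDH2	-1.64	-2.10	-0.26	-0.17	-0.65	-0.75	-1.02	-1.19	-0.81	-0.23	-0.84	-0.36
ENO1	0.96	0.33	1.00	1.48	1.14	0.64	1.27	1.22	0.19	1.12	0.17	1.53
EPM2A	-2.45	-0.96	-1.21	-0.79	-0.99	-1.30	-0.30	-1.17	-0.94	-1.10	-0.82	-2.00
GAPDH	0.67	1.05	0.90	1.29	0.56	1.50	1.35	1.72	0.08	0.64	0.44	1.45
LDHA	0.62	0.56	0.72	1.50	1.31	1.71	0.05	1.36	0.42	0.85	0.07	1.38
MPC1	-0.62	-0.38	-0.96	-0.69	-0.82	-1.56	-0.85	-0.37	-0.19	-0.42	-0.79	-0.38
PDHA2	NA	1.13	1.88	2.99	1.65	2.27	3.72	3.43	0.73	2.92	1.35	1.73
PFKFB4	2.39	1.26	0.84	1.15	1.65	2.45	2.43	0.81	0.21	0.11	0.18	2.33
PHKG2	0.71	1.12	0.48	0.95	1.01	0.28	0.86	0.86	0.26	0.96	0.31	1.01
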