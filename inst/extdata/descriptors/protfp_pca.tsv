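# name: ProtFP_PCA8
# kind: physicochemical-PCA
# source: van Westen et al. (2013) J Cheminform 5:41, principal components of 58 curated AAindex properties
# components: PC1,PC2,PC3,PC4,PC5,PC6,PC7,PC8
# variance_fractions: 0.43,0.24,0.08,0.06,0.04,0.03,0.03,0.02
# cumulative_fractions: 0.43,0.67,0.75,0.81,0.85,0.88,0.90,0.92
AA	PC1	PC2	PC3	PC4	PC5	PC6	PC7	PC8
A	-0.10	-4.94	-2.13	1.70	-0.39	1.06	-1.39	0.97
R	-2.79	6.60	1.21	2.07	1.67	0.76	0.00	0.32
N	-4.88	0.81	0.14	-0.14	1.23	-0.65	1.02	-1.94
D	-6.61	0.94	-3.04	-4.58	0.48	-1.31	0.10	0.94
C	4.62	-3.54	1.50	-1.26	3.27	-0.34	-0.47	-0.23
Q	-3.95	2.88	-0.83	0.52	0.90	0.55	-0.08	0.64
E	-5.10	2.20	-3.59	-2.26	-2.14	1.35	-0.45	-1.31
G	-5.70	-8.72	4.18	-1.35	-0.31	2.91	0.32	-0.11
H	0.17	2.14	1.20	0.71	1.16	-0.38	-1.85	-2.79
I	6.58	-1.73	-2.49	1.09	-0.34	-0.28	1.97	-0.92
L	5.76	-1.33	-1.71	0.63	-1.70	0.71	-0.05	-0.51
K	-4.99	5.00	0.70	3.00	-1.23	1.41	0.19	0.87
M	5.11	0.19	-1.02	0.15	0.13	-0.30	-2.95	0.50
F	6.76	0.88	0.89	-1.12	-0.49	-0.55	-0.87	1.05
P	-3.82	-2.31	3.45	1.00	-3.22	-3.54	-0.36	-0.30
S	-4.57	-2.55	-0.67	1.11	0.99	-1.02	0.11	0.65
T	-2.00	-1.77	-0.70	1.02	1.06	-1.20	0.74	1.65
W	7.33	4.55	2.77	-2.41	-1.08	1.04	0.23	0.59
Y	3.14	3.59	2.45	-1.27	-0.06	-0.29	1.99	0.30
V	5.04	-2.90	-2.29	1.38	0.06	0.08	1.79	-0.38
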