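# name: BLOSUM
# kind: substitution-derived
# source: Georgiev (2009) J Comput Biol 16:703-723; VARIMAX-analysed physicochemical properties projected through the BLOSUM62 substitution matrix
# components: BL1,BL2,BL3,BL4,BL5,BL6,BL7,BL8,BL9,BL10
AA	BL1	BL2	BL3	BL4	BL5	BL6	BL7	BL8	BL9	BL10
A	-0.57	0.39	-0.96	-0.61	-0.69	0.21	-0.48	0.47	0.01	0.26
R	-0.40	-0.83	-0.61	1.26	-0.28	-0.13	0.13	-0.20	-0.68	-0.39
N	-0.70	-0.63	-1.47	1.02	1.06	-0.66	-0.37	-0.12	0.45	0.61
D	-1.62	-0.52	-0.67	1.02	1.47	-0.78	-0.30	-0.75	1.27	-0.94
C	0.07	2.04	0.65	-1.13	-0.39	-0.04	-0.77	1.13	-0.23	-0.42
Q	-0.05	-1.50	-0.67	0.49	0.21	-0.71	-0.05	-0.51	0.27	1.84
E	-0.64	-1.59	-0.39	0.69	1.04	-0.33	-0.28	-0.93	0.93	0.06
G	-0.90	0.87	-0.36	1.08	1.95	-0.38	0.17	0.48	-0.58	-0.40
H	0.73	-0.67	-0.42	1.13	0.99	-1.45	0.29	0.31	-0.55	-0.10
I	0.59	0.79	0.44	-1.78	-0.93	-0.05	0.28	-0.55	0.00	-0.10
L	0.65	0.84	0.25	-0.99	-1.90	0.12	-0.25	0.26	-0.20	0.21
K	-0.64	-1.19	-0.65	0.68	-0.13	-0.77	0.22	0.10	-1.11	1.09
M	0.76	0.05	0.06	-0.62	-1.59	0.04	-0.46	0.00	0.65	0.99
F	1.12	0.49	1.22	-0.99	0.27	0.27	0.19	0.39	0.07	0.41
P	-0.36	-1.82	1.03	0.30	1.33	1.36	0.43	0.46	-0.53	0.06
S	-0.80	-0.04	-1.10	0.32	0.22	0.44	0.49	0.49	0.07	0.20
T	-0.39	0.08	-0.75	-0.35	-0.75	0.02	0.54	0.15	0.54	0.03
W	1.38	1.69	1.91	1.07	0.71	1.00	-0.47	0.09	0.45	-1.07
Y	1.75	0.11	1.19	0.55	0.79	-0.47	0.31	-0.59	0.04	-0.65
V	-0.02	0.87	0.32	-1.53	-1.41	0.10	0.55	-0.39	0.05	-0.19
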