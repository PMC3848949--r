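# name: FASGAI
# kind: factor-analysis
# source: Liang & Li (2007) QSAR Comb Sci 26:754-763; factor analysis of 335 physicochemical properties of the 20 natural amino acids
# components: F1,F2,F3,F4,F5,F6
# cumulative_fractions_total: 0.84
# notes: F1 hydrophobicity, F2 alpha/turn propensity, F3 bulkiness, F4 compositional index, F5 local flexibility, F6 electronic properties
AA	F1	F2	F3	F4	F5	F6
A	0.157	0.535	-0.935	-0.205	0.322	-0.225
R	-1.092	0.215	1.026	0.721	-0.209	1.460
N	-0.949	-0.255	-0.234	0.405	0.672	0.149
D	-1.127	-0.662	-0.544	0.715	0.210	-0.907
C	0.471	-0.744	-0.217	1.081	-0.316	-0.546
Q	-0.745	0.240	0.371	0.304	0.634	0.637
E	-1.086	-0.078	-0.061	0.388	-0.179	-1.209
G	-0.614	0.041	-1.838	-0.821	1.348	-0.063
H	-0.305	-0.365	0.566	1.002	-0.029	0.768
I	1.240	0.762	-0.164	-0.618	-0.654	0.034
L	1.020	1.056	-0.051	-0.595	-0.246	0.155
K	-1.174	0.468	0.428	-0.042	0.327	1.248
M	0.951	0.399	0.434	0.349	-0.514	0.258
F	1.279	-0.131	0.696	-0.494	-0.347	-0.185
P	-0.407	-2.042	-0.339	-1.031	0.391	0.178
S	-0.591	-0.008	-0.868	-0.023	0.745	-0.231
T	-0.379	0.194	-0.497	-0.278	0.133	-0.112
W	1.128	-0.347	1.955	0.318	-0.645	-0.270
Y	0.459	-0.552	1.060	0.043	-0.310	-0.584
V	0.767	0.817	-0.459	-0.385	-0.442	-0.350
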