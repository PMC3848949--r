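# name: STscales
# kind: topological-PCA
# source: Yang et al. (2010) Amino Acids 38:805-816; PCA of 827 structural/topological properties of 167 amino acids
# components: ST1,ST2,ST3,ST4,ST5,ST6,ST7,ST8
# cumulative_fractions_total: 0.715
# notes: component count follows the original publication (8); a contemporary summary table transposes the T-/ST-scales counts
AA	ST1	ST2	ST3	ST4	ST5	ST6	ST7	ST8
A	-1.552	-0.791	-0.627	0.237	-0.461	-2.229	0.283	1.221
R	-0.059	0.731	-0.013	-0.096	-0.253	0.300	1.256	0.854
N	-0.888	-0.057	-0.651	-0.214	0.917	0.164	-0.140	-0.166
D	-1.345	-0.603	-1.107	0.206	-0.014	0.672	-0.479	-0.649
C	-1.276	-0.401	0.134	0.859	-0.196	-0.720	0.639	-0.857
Q	-0.693	0.129	-0.184	-0.030	0.035	0.192	0.315	0.157
E	-0.900	0.258	-0.911	-0.156	-0.019	1.910	-0.986	0.618
G	-1.844	-0.018	-0.184	0.573	-0.728	-3.317	0.259	0.439
H	-0.225	0.361	0.079	-1.037	0.568	0.273	1.208	-0.001
I	-0.785	-1.010	-0.349	-0.097	-0.402	1.091	-0.139	-0.764
L	-0.826	-0.379	0.038	-0.059	-0.625	1.025	-0.229	-0.129
K	-0.504	0.245	0.297	-0.065	-0.387	1.011	0.525	0.553
M	-0.693	0.498	0.658	0.457	-0.231	1.064	0.248	-0.778
F	0.331	-0.440	-0.544	-0.533	-0.029	-0.225	0.907	-0.390
P	-1.049	-0.407	-0.067	-0.066	-0.813	-0.890	0.021	-0.894
S	-1.343	-0.311	-0.917	-0.049	0.549	-1.533	0.166	0.280
T	-1.061	-0.928	-0.911	-0.063	0.538	-0.775	-0.147	-0.717
W	0.853	0.039	0.260	-1.163	0.160	-0.202	1.010	0.195
Y	0.308	0.569	1.100	-0.464	0.523	-0.249	-0.141	-0.354
V	-1.133	-0.893	-0.325	0.303	-0.561	-0.175	-0.020	-0.311
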