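# name: ProtFP_Feature
# kind: feature
# source: van Westen et al. (2013) J Cheminform 5:41; hashed single-integer amino-acid fingerprint
# components: Feature
# notes: hash function not re-implemented; values are authoritative lookup constants
AA	Feature
A	1169372512
R	1636879004
N	-1593568836
D	1957532765
C	892384356
Q	-1986194934
E	558044215
G	-176196525
H	-1970548995
I	-1784790725
L	-590269326
K	268201585
M	-188476976
F	-1561345091
P	-576206913
S	-1481898440
T	-266397547
W	-816166777
Y	1237879003
V	-58134849
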