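# name: Zscales_Binned
# kind: binned
# source: binned classification over the Sandberg et al. (1998) Z-scales; class boundaries chosen so that every natural amino acid has a unique bit pattern
# notes: lipophilicity classes run inversely to Z1 (low Z1 = lipophilic); a residue scores 1 in the class whose [lower, upper) interval contains its Z value
scale	zscale	label	lower	upper
Lipophilicity	Z1	High	-Inf	-2.0
Lipophilicity	Z1	MediumHigh	-2.0	0.5
Lipophilicity	Z1	MediumLow	0.5	2.0
Lipophilicity	Z1	Low	2.0	Inf
Size	Z2	Small	-Inf	-1.8
Size	Z2	MediumSmall	-1.8	0.5
Size	Z2	MediumLarge	0.5	2.4
Size	Z2	Large	2.4	Inf
ElectronicProperties	Z3	Low	-Inf	-1.8
ElectronicProperties	Z3	MediumLow	-1.8	-0.5
ElectronicProperties	Z3	MediumHigh	-0.5	0.3
ElectronicProperties	Z3	High	0.3	Inf
Electronegativity	Z4	Low	-Inf	-1.5
Electronegativity	Z4	MediumLow	-1.5	0.0
Electronegativity	Z4	MediumHigh	0.0	1.9
Electronegativity	Z4	High	1.9	Inf
Electrophilicity	Z5	Low	-Inf	-0.9
Electrophilicity	Z5	MediumLow	-0.9	0.3
Electrophilicity	Z5	MediumHigh	0.3	1.0
Electrophilicity	Z5	High	1.0	Inf
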