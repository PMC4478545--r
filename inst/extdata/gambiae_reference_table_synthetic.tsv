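# Synthetic reference codon usage table for Anopheles gambiae transgene design.
# SYNTHETIC STAND-IN: constructed, not transcribed from published counts.
# Emulates codon preference in a small set of 9 medium-to-highly expressed
# A. gambiae genes totalling 10,160 codons (10,151 sense + 9 terminal stops):
# GC-ending codons preferred; Leu TTA and Arg AGA/AGG rare (< 10% within their
# amino acid). Columns: codon, aa, count, freq_within_aa, per_1000.
codon	aa	count	freq_within_aa	per_1000
AAA	K	178	0.280315	17.519685
AAC	N	292	0.648889	28.740157
AAG	K	457	0.719685	44.980315
AAT	N	158	0.351111	15.551181
ACA	T	101	0.179396	9.940945
ACC	T	203	0.360568	19.980315
ACG	T	146	0.259325	14.370079
ACT	T	113	0.20071	11.122047
AGA	R	38	0.070111	3.740157
AGC	S	143	0.199721	14.074803
AGG	R	44	0.081181	4.330709
AGT	S	86	0.120112	8.464567
ATA	I	81	0.149446	7.972441
ATC	I	282	0.520295	27.755906
ATG	M	235	1	23.129921
ATT	I	179	0.330258	17.61811
CAA	Q	123	0.300733	12.106299
CAC	H	153	0.651064	15.059055
CAG	Q	286	0.699267	28.149606
CAT	H	82	0.348936	8.070866
CCA	P	113	0.220703	11.122047
CCC	P	133	0.259766	13.090551
CCG	P	153	0.298828	15.059055
CCT	P	113	0.220703	11.122047
CGA	R	65	0.119926	6.397638
CGC	R	184	0.339483	18.110236
CGG	R	92	0.169742	9.055118
CGT	R	119	0.219557	11.712598
CTA	L	57	0.06051	5.610236
CTC	L	226	0.239915	22.244094
CTG	L	377	0.400212	37.106299
CTT	L	132	0.140127	12.992126
GAA	E	213	0.330233	20.964567
GAC	D	314	0.579336	30.905512
GAG	E	432	0.669767	42.519685
GAT	D	228	0.420664	22.440945
GCA	A	110	0.139594	10.826772
GCC	A	299	0.379442	29.429134
GCG	A	158	0.200508	15.551181
GCT	A	221	0.280457	21.751969
GGA	G	149	0.220414	14.665354
GGC	G	284	0.420118	27.952756
GGG	G	67	0.099112	6.594488
GGT	G	176	0.260355	17.322835
GTA	V	61	0.09037	6.003937
GTC	V	175	0.259259	17.224409
GTG	V	290	0.42963	28.543307
GTT	V	149	0.220741	14.665354
TAA	*	5	0.555556	0.492126
TAC	Y	210	0.640244	20.669291
TAG	*	2	0.222222	0.19685
TAT	Y	118	0.359756	11.614173
TCA	S	79	0.110335	7.775591
TCC	S	158	0.22067	15.551181
TCG	S	143	0.199721	14.074803
TCT	S	107	0.149441	10.531496
TGA	*	2	0.222222	0.19685
TGC	C	129	0.701087	12.69685
TGG	W	123	1	12.106299
TGT	C	55	0.298913	5.413386
TTA	L	28	0.029724	2.755906
TTC	F	266	0.650367	26.181102
TTG	L	122	0.129512	12.007874
TTT	F	143	0.349633	14.074803
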