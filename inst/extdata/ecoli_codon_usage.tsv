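codon	aa	fraction
TTT	F	0.5721649484536083
TTC	F	0.4278350515463918
TTA	L	0.1310084825636192
TTG	L	0.1291234684260132
CTT	L	0.1036757775683318
CTC	L	0.1036757775683318
CTA	L	0.0367577756833176
CTG	L	0.4957587181903865
ATT	I	0.5075376884422110
ATC	I	0.4204355108877722
ATA	I	0.0720268006700167
ATG	M	1.0000000000000000
GTT	V	0.2581100141043723
GTC	V	0.2157968970380818
GTA	V	0.1537376586741890
GTG	V	0.3723554301833568
TCT	S	0.1462994836488812
TCC	S	0.1480206540447504
TCA	S	0.1239242685025818
TCG	S	0.1531841652323580
AGT	S	0.1514629948364888
AGC	S	0.2771084337349398
CCT	P	0.1587301587301587
CCC	P	0.1247165532879819
CCA	P	0.1904761904761905
CCG	P	0.5260770975056689
ACT	T	0.1669758812615955
ACC	T	0.4341372912801484
ACA	T	0.1317254174397031
ACG	T	0.2671614100185529
GCT	A	0.1619047619047619
GCC	A	0.2698412698412698
GCA	A	0.2126984126984127
GCG	A	0.3555555555555556
TAT	Y	0.5704225352112676
TAC	Y	0.4295774647887324
CAT	H	0.5707964601769911
CAC	H	0.4292035398230088
CAA	Q	0.3469387755102041
CAG	Q	0.6530612244897959
AAT	N	0.4492385786802031
AAC	N	0.5507614213197970
AAA	K	0.7653758542141229
AAG	K	0.2346241457858770
GAT	D	0.6269531250000000
GAC	D	0.3730468750000000
GAA	E	0.6888111888111887
GAG	E	0.3111888111888112
TGT	C	0.4482758620689655
TGC	C	0.5517241379310345
TGG	W	1.0000000000000000
CGT	R	0.3786231884057971
CGC	R	0.3985507246376812
CGA	R	0.0652173913043478
CGG	R	0.0978260869565218
AGA	R	0.0380434782608696
AGG	R	0.0217391304347826
GGT	G	0.3365122615803814
GGC	G	0.4032697547683924
GGA	G	0.1089918256130790
GGG	G	0.1512261580381471
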