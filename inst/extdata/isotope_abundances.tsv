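element	shift	mass	abundance
C	0	12.0	0.9893
C	1	13.0033548378	0.0107
H	0	1.00782503207	0.999885
H	1	2.01410177785	0.000115
N	0	14.0030740048	0.99636
N	1	15.0001088982	0.00364
O	0	15.9949146196	0.99757
O	1	16.9991317012	0.00038
O	2	17.9991610041	0.00205
S	0	31.97207100	0.9499
S	1	32.97145876	0.0075
S	2	33.96786690	0.0425
P	0	30.97376163	1.0
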