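element	isotope_mass	abundance	label
H	1.00782503207	0.999885	0
H	2.01410177785	0.000115	1
C	12.0000000000	0.9893	0
C	13.00335483507	0.0107	1
N	14.0030740048	0.99636	0
N	15.0001088982	0.00364	1
O	15.99491461956	0.99757	0
O	16.99913170	0.00038	0
O	17.99916100	0.00205	1
S	31.97207100	0.9499	0
S	32.97145876	0.0075	0
S	33.96786690	0.0425	0
S	35.96708076	0.0001	0
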