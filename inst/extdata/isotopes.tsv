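element	mass	abundance
H	1.0078250319	0.999885
H	2.0141017780	0.000115
C	12.0000000000	0.9893
C	13.0033548378	0.0107
N	14.0030740052	0.99632
N	15.0001088984	0.00368
O	15.9949146221	0.99757
O	16.9991315000	0.00038
O	17.9991604000	0.00205
P	30.9737615100	1.0
S	31.9720706900	0.9493
S	32.9714585000	0.0076
S	33.9678668300	0.0429
S	35.9670808800	0.0002
Na	22.9897696700	1.0
K	38.9637069000	0.932581
K	39.9639987000	0.000117
K	40.9618260000	0.067302
Cl	34.9688527100	0.7578
Cl	36.9659026000	0.2422
F	18.9984032000	1.0
Br	78.9183376000	0.5069
Br	80.9162910000	0.4931
I	126.9044680000	1.0
Se	73.9224766000	0.0089
Se	75.9192141000	0.0937
Se	76.9199146000	0.0763
Se	77.9173095000	0.2377
Se	79.9165218000	0.4961
Se	81.9167000000	0.0873
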