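element	weight
H	1.00794
C	12.0107
N	14.0067
O	15.9994
P	30.973762
S	32.065
Na	22.98977
K	39.0983
Cl	35.453
F	18.9984032
Br	79.904
I	126.90447
Se	78.96
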