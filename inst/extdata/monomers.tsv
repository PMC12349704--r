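code	formula	class	thiol
Gly	C2H3NO	amino-acid	FALSE
Ala	C3H5NO	amino-acid	FALSE
Ser	C3H5NO2	amino-acid	FALSE
Pro	C5H7NO	amino-acid	FALSE
Val	C5H9NO	amino-acid	FALSE
Thr	C4H7NO2	amino-acid	FALSE
Cys	C3H5NOS	amino-acid	TRUE
Leu	C6H11NO	amino-acid	FALSE
Ile	C6H11NO	amino-acid	FALSE
Asn	C4H6N2O2	amino-acid	FALSE
Asp	C4H5NO3	amino-acid	FALSE
Gln	C5H8N2O2	amino-acid	FALSE
Glu	C5H7NO3	amino-acid	FALSE
Lys	C6H12N2O	amino-acid	FALSE
Met	C5H9NOS	amino-acid	FALSE
His	C6H7N3O	amino-acid	FALSE
Phe	C9H9NO	amino-acid	FALSE
Arg	C6H12N4O	amino-acid	FALSE
Tyr	C9H9NO2	amino-acid	FALSE
Trp	C11H10N2O	amino-acid	FALSE
Pyr	C5H5NO2	amino-acid	FALSE
Glp	C5H5NO2	amino-acid	FALSE
Aib	C4H7NO	amino-acid	FALSE
Orn	C5H10N2O	amino-acid	FALSE
Sar	C3H5NO	amino-acid	FALSE
Msa	C12H15NO	amino-acid	FALSE
2Nal	C13H11NO	amino-acid	FALSE
Ser-tBu	C7H13NO2	amino-acid	FALSE
HisBzl	C13H13N3O	amino-acid	FALSE
Tyr(Me)	C10H11NO2	amino-acid	FALSE
Tyr(Et)	C11H13NO2	amino-acid	FALSE
Met(O2)	C5H9NO3S	amino-acid	FALSE
deamino-Cys	C3H5OS	amino-acid	TRUE
dA	C10H12N5O5P	nucleotide	FALSE
dC	C9H12N3O6P	nucleotide	FALSE
dG	C10H12N5O6P	nucleotide	FALSE
dT	C10H13N2O7P	nucleotide	FALSE
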