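compound	rt_min	mam_score	mam_matches	mam_mismatches	mam_metmatches	mim_score	mim_matches	mim_mismatches	mim_metmatches
calcitonin	1.86	445.4	2	1	13	126.1	1	0	0
calcitonin	1.91	928.3	10	0	17	523.4	6	0	0
calcitonin	2.45	914.2	12	2	28	175.5	2	0	1
calcitonin	2.47	1062.3	13	1	40	197.1	0	0	0
calcitonin	2.52	1864.0	17	1	19	454.9	6	0	0
calcitonin	2.99	1177.4	23	3	30	234.5	2	0	0
insulin	2.06	509.6	3	0	0	NA	NA	NA	NA
insulin	7.78	1017.5	6	0	18	132.9	2	0	12
insulin	8.08	760.3	6	0	5	NA	NA	NA	NA
insulin	9.14	816.3	6	0	8	253.3	4	0	9
insulin	9.32	767.5	6	0	2	NA	NA	NA	NA
insulin	9.65	767.1	6	0	9	243.6	4	2	10
insulin	9.80	874.0	6	0	4	278.7	4	0	5
insulin	10.38	992.6	9	0	2	NA	NA	NA	NA
insulin	11.17	792.4	6	0	4	319.0	2	0	3
insulin	11.43	737.5	6	0	4	223.8	4	0	4
insulin	11.69	509.6	3	0	0	210.1	4	1	7
insulin	12.39	789.8	6	0	8	NA	NA	NA	NA
insulin	15.65	NA	NA	NA	NA	138.9	2	0	0
aso	7.17	2654.9	31	0	2	835.9	15	0	0
aso	8.62	2547.5	32	0	5	896.8	15	0	0
aso	14.42	2250.2	31	0	11	NA	NA	NA	NA
aso	16.36	4445.7	62	6	33	788.3	35	0	3
aso	17.11	4019.8	46	4	19	NA	NA	NA	NA
aso	17.59	5056.3	67	3	18	426.1	25	0	2
aso	17.84	1778.9	24	0	0	NA	NA	NA	NA
aso	17.90	6171.2	101	6	19	541.9	NA	NA	NA
aso	17.92	4081.9	62	1	4	561.3	5	0	3
aso	17.95	8142.5	112	5	38	NA	NA	NA	NA
aso	18.26	5423.3	83	2	21	371.5	25	0	1
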